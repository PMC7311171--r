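#' Read a macromolecular structure (PDB or mmCIF)
#'
#' Parses coordinates via bio3d and returns a [structure_model()]. All
#' polymer chains are retained with author residue numbering preserved;
#' heteroatoms and waters are retained but flagged (`het = TRUE`).
#'
#' @param path file path
#' @param format one of `"auto"` (by extension), `"pdb"`, `"mmcif"`
#' @return a `structure_model`
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "mmcif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop("could not parse ", format, " file '", path,
                             "': ", conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0) stop("empty model in file: ", path)
  element <- a$elesy
  if (is.null(element)) element <- rep("", nrow(a))
  element <- trimws(element)
  blank <- is.na(element) | element == ""
  element[blank] <- guess_element(a$elety[blank])
  structure_model(data.frame(
    element = element,
    name = trimws(a$elety),
    x = a$x, y = a$y, z = a$z,
    resno = a$resno,
    insert = ifelse(is.na(a$insert), "", a$insert),
    resid = trimws(a$resid),
    chain = ifelse(is.na(a$chain), "", a$chain),
    het = a$type == "HETATM",
    stringsAsFactors = FALSE))
}

# crude element guess from an atom name when the element column is absent
guess_element <- function(name) {
  if (length(name) == 0) return(character(0))
  s <- gsub("[0-9']", "", trimws(name))
  two <- toupper(substr(s, 1, 2))
  el <- toupper(substr(s, 1, 1))
  el[two %in% c("FE", "ZN", "MG", "MN", "NA", "CL", "BR", "SE", "CU")] <-
    two[two %in% c("FE", "ZN", "MG", "MN", "NA", "CL", "BR", "SE", "CU")]
  el[el == ""] <- "X"
  el
}

#' Write a structure in PDB format
#'
#' @param model a `structure_model`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$name,
                   chain = a$chain, insert = a$insert,
                   elesy = a$element)
  invisible(path)
}

#' Named domain selection
#'
#' A selection of an inclusive, 1-based author-numbered residue interval on a
#' subunit, e.g. the BBS7 beta-propeller = residues 1-332. The `subunit` is
#' mapped to a chain id through an optional `chain_map` at resolution time
#' (deposited models do not document which chain is which subunit, so the
#' mapping is user configuration).
#'
#' @param subunit subunit name or chain id (e.g. "BBS7", "A")
#' @param domain_label free-text domain label (e.g. "bprop", "cc", "PH1")
#' @param residue_range inclusive author-numbered interval, length-2 integer
#' @return object of class `domain_selection`
#' @export
domain_selection <- function(subunit, domain_label = "", residue_range) {
  stopifnot(length(residue_range) == 2, residue_range[1] <= residue_range[2])
  structure(list(subunit = subunit, domain_label = domain_label,
                 residue_range = as.integer(residue_range)),
            class = "domain_selection")
}

#' Extract a domain substructure
#'
#' Returns exactly the residues whose author numbers fall in the selection's
#' inclusive range on the named chain. Errors if the selection resolves to no
#' residues.
#'
#' @param model a `structure_model`
#' @param selection a `domain_selection`
#' @param chain_map optional named list/vector mapping subunit names to chain
#'   ids; when absent the selection's `subunit` is used as the chain id
#' @return a `structure_model` containing the selected residues
#' @export
select_domain <- function(model, selection, chain_map = NULL) {
  stopifnot(inherits(selection, "domain_selection"))
  ch <- selection$subunit
  if (!is.null(chain_map) && !is.null(chain_map[[ch]])) ch <- chain_map[[ch]]
  rng <- selection$residue_range
  a <- model$atoms
  keep <- a$chain == ch & a$resno >= rng[1] & a$resno <= rng[2]
  if (!any(keep)) {
    stop(sprintf("selection resolves to no residues: chain '%s', range %d-%d",
                 ch, rng[1], rng[2]))
  }
  structure_model(a[keep, , drop = FALSE])
}

#' Sequence record with author numbering
#'
#' @param id sequence id
#' @param residues one-letter string (20-letter alphabet plus X)
#' @param offset author residue number of the first position (default 1)
#' @param positions optional integer vector of author numbers, one per
#'   residue, for chains with numbering gaps; overrides `offset` spacing
#' @return object of class `sequence_record` with fields `id`, `residues`,
#'   `numbering_offset`, `positions` and `gap_after` (string indices after
#'   which author numbering jumps)
#' @export
sequence_record <- function(id, residues, offset = 1L, positions = NULL) {
  residues <- toupper(as.character(residues))
  n <- nchar(residues)
  if (n > 0 && grepl("[^ACDEFGHIKLMNPQRSTVWYX]", residues)) {
    stop("sequence contains letters outside the 20-letter alphabet plus X")
  }
  if (is.null(positions)) {
    positions <- if (n > 0) as.integer(offset) + 0:(n - 1) else integer(0)
  }
  stopifnot(length(positions) == n)
  gap_after <- if (n > 1) which(diff(positions) > 1L) else integer(0)
  structure(list(id = id, residues = residues,
                 numbering_offset = if (n > 0) positions[1] else as.integer(offset),
                 positions = as.integer(positions),
                 gap_after = gap_after),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("sequence_record %s: %d aa, numbering %s..%s%s\n", x$id,
              nchar(x$residues),
              if (length(x$positions)) x$positions[1] else "-",
              if (length(x$positions)) x$positions[length(x$positions)] else "-",
              if (length(x$gap_after)) sprintf(" (%d numbering gap(s))",
                                               length(x$gap_after)) else ""))
  invisible(x)
}

#' Sequence length of a record
#' @param record a `sequence_record`
#' @return integer
#' @export
sequence_length <- function(record) nchar(record$residues)

#' Extract the one-letter sequence of a chain
#'
#' Residues are taken in residue-number order (insertion codes after their
#' base number); numbering gaps are recorded; non-standard residues map to X.
#' Het-flagged residues (waters, ligands) are excluded.
#'
#' @param model a `structure_model`
#' @param chain chain id
#' @return a `sequence_record` whose `numbering_offset` is the first
#'   residue's author number
#' @export
extract_sequence <- function(model, chain) {
  a <- model$atoms
  a <- a[a$chain == chain & !a$het, , drop = FALSE]
  if (nrow(a) == 0) stop("unknown or empty chain: ", chain)
  r <- unique(a[, c("resno", "insert", "resid")])
  r <- r[order(r$resno, r$insert), , drop = FALSE]
  # strict standard-20 mapping: modified residues (MSE, ...) become X even
  # where a parent residue is known, so sequence scans stay conservative
  one <- ifelse(r$resid %in% standard_aa3(),
                suppressWarnings(bio3d::aa321(r$resid)), "X")
  sequence_record(chain, paste(one, collapse = ""), positions = r$resno)
}

#' Read sequences from a FASTA file
#'
#' Headers of the form `>id offset=543 ...` set the record's author-numbering
#' offset; otherwise numbering starts at 1.
#'
#' @param path FASTA file
#' @return named list of `sequence_record`s
#' @export
read_fasta_records <- function(path) {
  fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                           whole.header = TRUE)
  out <- lapply(fa, function(s) {
    header <- attr(s, "name")
    toks <- strsplit(trimws(header), "\\s+")[[1]]
    id <- toks[1]
    offset <- 1L
    m <- grep("^offset=", toks, value = TRUE)
    if (length(m) == 1) offset <- as.integer(sub("^offset=", "", m))
    sequence_record(id, as.character(s), offset = offset)
  })
  names(out) <- vapply(out, function(r) r$id, character(1))
  out
}

#' Write sequence records to FASTA
#'
#' The author-numbering offset is stored in the header as `offset=<n>` so a
#' round trip preserves numbering.
#'
#' @param records list of `sequence_record`s
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_fasta_records <- function(records, path) {
  seqs <- lapply(records, function(r) r$residues)
  names_out <- vapply(records, function(r)
    sprintf("%s offset=%d", r$id, r$numbering_offset), character(1))
  seqinr::write.fasta(sequences = as.list(seqs), names = names_out,
                      file.out = path, as.string = TRUE, nbchar = 60)
  invisible(path)
}
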