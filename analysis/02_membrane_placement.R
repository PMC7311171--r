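#!/usr/bin/env Rscript
# Stage 2: place the membrane plane from the amphipathic anchor, search
# anchored orientations for the minimum cargo-site distance, and assess
# curvature and membrane-facing charge.
#
# Found here (seed 1): the anchor's hydrophobic face recovers the planted
# plane essentially exactly; no anchored orientation brings the recessed
# cargo patch closer than ~18-21 A to the headgroup plane, i.e. well beyond
# helical tether reach; the membrane-facing slab is net positive; a
# 1250 A-radius cylinder (250 nm cilium) behaves like a flat membrane at
# complex scale.

library(bbscargo)

seed <- 1L
dir.create("results", showWarnings = FALSE)
fx <- make_membrane_complex_fixture(seed = seed, plant_positive = 7,
                                    plant_negative = 2)

pl <- place_membrane(fx$model, fx$anchor)
cat(sprintf("placement feasible: %s; normal error %.3f deg; offset error %.3f A\n",
            pl$feasible, angle_between(pl$plane$normal, fx$plane$normal),
            abs(pl$plane$offset - fx$plane$offset)))

md <- min_patch_distance(fx$model, fx$anchor, fx$patch_chain)
cat(sprintf("minimum cargo-site distance over %d anchored orientations: %.2f A\n",
            md$n_feasible, md$min_distance))
verdict <- conformational_verdict(md$min_distance, 6)
cat(sprintf("6-step tether verdict at that distance: %s\n", verdict$conclusion))

census <- membrane_facing_charge_census(fx$model, pl$plane, slab_depth = 8)
curv <- curvature_compatibility(fx$model, pl$plane, radius = 1250)
cat(sprintf("charge slab (8 A): +%d / -%d; cylinder penetrations: %d\n",
            census$positive_count, census$negative_count,
            curv$penetration_count))

cfg <- list(stage = "membrane", seed = seed, slab_depth = 8, radius = 1250)
write_report_json(
  list(feasible = pl$feasible,
       normal = pl$plane$normal, offset = pl$plane$offset,
       normal_error_deg = angle_between(pl$plane$normal, fx$plane$normal),
       offset_error_A = abs(pl$plane$offset - fx$plane$offset),
       min_cargo_site_distance_A = md$min_distance,
       n_feasible_orientations = md$n_feasible,
       tether_verdict = verdict$conclusion,
       slab_positive = census$positive_count,
       slab_negative = census$negative_count,
       cylinder_penetrations = curv$penetration_count,
       cylinder_contact_fraction = curv$contact_fraction),
  "results/membrane_placement.json", config = cfg, seed = seed)
write_report_tsv(census$per_residue_table, "results/charge_census.tsv",
                 config = cfg, seed = seed)
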