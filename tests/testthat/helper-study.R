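# Shared fixtures for the scaled-down 2D study conditions. Everything is
# generated in code; expensive objects are memoized for the duration of the
# test run.

.study_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.study_cache[[key]])) .study_cache[[key]] <- force(expr)
  .study_cache[[key]]
}

# one small 3D phantom pair used by tensor and solver tests
phantom_3d <- function() memo("ph3d", {
  ph <- generate_brain_phantom(c(32, 32, 32), 1, "two-shell", seed = 0)
  ph$unit <- build_tumor_tensor(ph$water, ph$map)
  ph
})

# non-convex 2D phantom for boundary and conservation tests
phantom_folded_2d <- function() memo("phf2d", {
  ph <- generate_brain_phantom(c(48, 48, 1), 1, "folded", seed = 3)
  ph$unit <- build_tumor_tensor(ph$water, ph$map)
  ph
})

# 2D study subjects: 48 x 48 voxels at 2.5 mm (120 mm field of view),
# alternating convex and folded geometries with a white-dominant core
# (white radius 80% of the gray shell) so that growth mostly happens in
# white matter, as in a real centrum-semiovale tumor
study_subjects <- function(n = 6, shape = c(48, 48, 1), spacing = 2.5) {
  subjects <- lapply(seq_len(n), function(i) {
    style <- if (i %% 2 == 0) "two-shell" else "folded"
    ext <- min(shape[shape > 1] * spacing)
    # shrink on very small grids so the folded shell keeps its margin
    gr <- min(0.375 * ext, (ext / 2 - 1.6 * spacing) / 1.12)
    ph <- generate_brain_phantom(shape, spacing, style, seed = 100 + i,
                                 gray_radius = gr, white_radius = 0.8 * gr)
    list(map = ph$map, unit_tensor = build_tumor_tensor(ph$water, ph$map))
  })
  names(subjects) <- sprintf("s%02d", seq_len(n))
  subjects
}

# main 2D study dataset: 6 subjects x 30 tumors, last subject held out
study_dataset <- function() memo("study_ds", {
  subjects <- study_subjects()
  ds <- build_dataset(subjects, 30, seed = 42,
                      config = simulation_config(dt = 2))
  attr(ds, "subjects") <- subjects
  ds
})

study_unit_tensors <- function(ds = study_dataset()) {
  lapply(attr(ds, "subjects"), `[[`, "unit_tensor")
}

# one readily available synthetic record on the first study subject
study_record <- function() memo("study_rec", {
  subjects <- study_subjects(1)
  rec <- synthesize_tumor(subjects[[1]]$map, subjects[[1]]$unit_tensor,
                          seed = 7, config = simulation_config(dt = 2),
                          subject_id = "s01")
  attr(rec, "subject") <- subjects[[1]]
  rec
})

# brute-force R implementations used as independent oracles
brute_hausdorff <- function(A, B) {
  d2 <- function(P, Q) {
    apply(P, 1, function(p) sqrt(min(colSums((t(Q) - p)^2))))
  }
  max(max(d2(A, B)), max(d2(B, A)))
}

brute_assd <- function(A, B) {
  d2 <- function(P, Q) {
    apply(P, 1, function(p) sqrt(min(colSums((t(Q) - p)^2))))
  }
  (sum(d2(A, B)) + sum(d2(B, A))) / (nrow(A) + nrow(B))
}

# symmetric 3x3 matrix from a 6-component row
sym33 <- function(cc) {
  matrix(c(cc[1], cc[2], cc[3],
           cc[2], cc[4], cc[5],
           cc[3], cc[5], cc[6]), 3, 3)
}
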