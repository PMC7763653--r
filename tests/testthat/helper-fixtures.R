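# shared fixtures: default panel/model are cheap to build, construct per test
# via these helpers so individual tests stay independent

fix_panel <- function() default_panel()
fix_model <- function(...) migration_model(...)

# a ladder + calibration under the default model
fix_calibration <- function(panel = fix_panel(), model = fix_model(),
                            seed = 1) {
  lad <- simulate_ladder_trace(panel, model, seed = seed)
  fit_calibration(lad, panel$ladder_sizes_bp)
}

# hand-built sized-peaks table (the shape size_peaks() returns)
sized_peaks_df <- function(size_bp, height_fu = rep(50, length(size_bp)),
                           time_s = seq_along(size_bp)) {
  structure(data.frame(time_s = time_s, height_fu = height_fu,
                       area = height_fu, size_bp = size_bp,
                       in_sizing_range = size_bp >= 25 & size_bp <= 1000),
            class = c("sized_peaks", "data.frame"))
}

# independent oracle: nearest-allele brute-force search over a repeat grid
brute_force_repeats <- function(locus, size, r_max = 200L) {
  r <- 1:r_max
  sizes <- locus$flank_offset_bp + locus$repeat_unit_bp * r
  r[which.min(abs(sizes - size))]
}

# independent oracle: linear scan over all loci of a set
brute_force_locus <- function(panel, set_id, size) {
  hits <- Filter(function(l) l$multiplex_set == set_id &&
                   size >= l$size_range_bp[1] && size <= l$size_range_bp[2],
                 panel$loci)
  if (length(hits)) hits[[1]]$name else NA_character_
}

# independent shared-allele count: explicit double loop with element removal
brute_force_shared <- function(a, b) {
  n <- 0L
  for (x in a) {
    i <- match(x, b)
    if (!is.na(i)) { n <- n + 1L; b <- b[-i] }
  }
  n
}

# simulate all four wells of a profile and call it back through the pipeline
roundtrip_profile <- function(profile, panel, model, seed, cal_seed = seed) {
  lad <- simulate_ladder_trace(panel, model, seed = cal_seed)
  wells <- simulate_profile_wells(panel, profile, model, seed = seed)
  profile_from_traces(lad, wells, panel, profile$sample)
}
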