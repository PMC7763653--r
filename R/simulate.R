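#' Electrophoretic migration model for the chip simulator
#'
#' Fragments of size \eqn{s} bp reach the detector at
#' \eqn{t(s) = t_0 + \mathrm{slope} \cdot \log_{10}(s)} seconds, a monotone
#' log-mobility law; each fragment produces a Gaussian peak in the time
#' domain whose height is proportional to its relative amount, on top of
#' i.i.d. Gaussian baseline noise. Optionally every fragment also produces a
#' stutter peak \code{stutter_bp} below it at \code{stutter_fraction} of its
#' height.
#'
#' @param t0 intercept, seconds.
#' @param slope migration slope, seconds per log10(bp); must be positive so
#'   larger fragments migrate later.
#' @param peak_sigma_s Gaussian peak standard deviation, seconds.
#' @param noise_sd_fu baseline noise standard deviation, fluorescence units.
#' @param stutter_fraction height of the stutter artifact relative to its
#'   parent peak, in [0, 1); 0 disables stutter.
#' @param stutter_bp stutter displacement in bp (one repeat unit below the
#'   allele for tetranucleotide panels).
#' @param dt_s sampling interval of the trace, seconds.
#' @param amount_scale_fu peak height (FU) of one unit of relative amount.
#' @param marker_height_fu height (FU) of the internal marker peaks.
#' @return An object of class \code{"migration_model"}.
#' @export
migration_model <- function(t0 = 10, slope = 60, peak_sigma_s = 0.1,
                            noise_sd_fu = 0.5, stutter_fraction = 0,
                            stutter_bp = 4, dt_s = 0.02,
                            amount_scale_fu = 50, marker_height_fu = 75) {
  stopifnot(slope > 0, peak_sigma_s > 0, noise_sd_fu >= 0,
            stutter_fraction >= 0, stutter_fraction < 1, dt_s > 0)
  structure(list(t0 = t0, slope = slope, peak_sigma_s = peak_sigma_s,
                 noise_sd_fu = noise_sd_fu,
                 stutter_fraction = stutter_fraction, stutter_bp = stutter_bp,
                 dt_s = dt_s, amount_scale_fu = amount_scale_fu,
                 marker_height_fu = marker_height_fu),
            class = "migration_model")
}

migration_time <- function(model, size_bp) model$t0 + model$slope * log10(size_bp)

electropherogram <- function(time_s, fu, well_kind = c("sample", "ladder"),
                             label = "") {
  well_kind <- match.arg(well_kind)
  stopifnot(length(time_s) == length(fu), !is.unsorted(time_s, strictly = TRUE),
            all(is.finite(fu)))
  structure(list(time_s = time_s, fu = fu, well_kind = well_kind,
                 label = label),
            class = "electropherogram")
}

#' @export
print.electropherogram <- function(x, ...) {
  cat(sprintf("Electropherogram '%s' (%s well): %d samples, %.2f-%.2f s, max %.1f FU\n",
              x$label, x$well_kind, length(x$time_s), min(x$time_s),
              max(x$time_s), max(x$fu)))
  invisible(x)
}

#' @export
plot.electropherogram <- function(x, ...) {
  plot(x$time_s, x$fu, type = "l", xlab = "migration time [s]",
       ylab = "fluorescence [FU]", main = x$label, ...)
}

#' @export
as.data.frame.electropherogram <- function(x, ...) {
  data.frame(time_s = x$time_s, fu = x$fu)
}

# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' PCR fragments produced by a profile in one multiplex set
#'
#' Expands the alleles of the set's loci into (size, relative amount)
#' fragments: a heterozygous locus contributes two fragments of unit amount,
#' a locus stored with a single allele contributes one fragment of double
#' amount (both chromosomes amplify the same product). Human-locus fragments
#' are produced only when the profile carries human alleles.
#'
#' @param panel an \code{"str_panel"}.
#' @param set_id multiplex set, 1..4.
#' @param profile an \code{\link{str_profile}}.
#' @return A data.frame with columns \code{locus}, \code{repeats},
#'   \code{size_bp}, \code{amount}.
#' @export
amplicons_for_profile <- function(panel, set_id, profile) {
  out <- list()
  for (loc in set_loci(panel, set_id)) {
    alleles <- if (loc$species == "human") profile$human_alleles
               else profile$calls[[loc$name]]
    if (is.null(alleles) || length(alleles) == 0L) next
    sizes <- predicted_size(loc, alleles)
    off <- sizes < loc$size_range_bp[1] | sizes > loc$size_range_bp[2]
    if (any(off))
      stop("allele ", paste(alleles[off], collapse = ", "), " at locus '",
           loc$name, "' predicts size ", paste(sizes[off], collapse = ", "),
           " bp outside the locus range [", loc$size_range_bp[1], ", ",
           loc$size_range_bp[2], "]", call. = FALSE)
    out[[loc$name]] <- data.frame(
      locus = loc$name, repeats = alleles, size_bp = sizes,
      amount = if (length(alleles) == 1L) 2 else 1)
  }
  if (!length(out))
    return(data.frame(locus = character(0), repeats = integer(0),
                      size_bp = numeric(0), amount = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$size_bp), , drop = FALSE]
}

gaussian_peaks <- function(time_s, centers, heights, sigma) {
  fu <- numeric(length(time_s))
  for (i in seq_along(centers))
    fu <- fu + heights[i] * exp(-0.5 * ((time_s - centers[i]) / sigma)^2)
  fu
}

#' Simulate one chip well from a fragment list
#'
#' Builds a sampled fluorescence trace containing the lower and upper
#' internal-marker peaks (present in every well), one Gaussian peak per
#' fragment at \code{t0 + slope * log10(size)}, optional stutter peaks, and
#' seeded baseline noise. The same seed always yields the identical trace.
#'
#' @param fragments data.frame with columns \code{size_bp} and \code{amount}
#'   (e.g. from \code{\link{amplicons_for_profile}}); may be empty.
#' @param model a \code{\link{migration_model}}.
#' @param seed integer RNG seed for the baseline noise.
#' @param lower_marker_bp,upper_marker_bp internal marker sizes, bp.
#' @param well_kind,label trace metadata.
#' @return An \code{"electropherogram"}.
#' @export
simulate_trace <- function(fragments, model, seed,
                           lower_marker_bp = 15, upper_marker_bp = 1500,
                           well_kind = "sample", label = "") {
  sizes <- fragments$size_bp
  amounts <- fragments$amount
  keep <- amounts > 0
  sizes <- sizes[keep]; amounts <- amounts[keep]
  if (any(sizes < lower_marker_bp | sizes > upper_marker_bp))
    stop("fragment size outside the internal-marker bounds [",
         lower_marker_bp, ", ", upper_marker_bp, "] bp", call. = FALSE)
  t_lo <- migration_time(model, lower_marker_bp)
  t_hi <- migration_time(model, upper_marker_bp)
  time_s <- seq(t_lo - 2, t_hi + 2, by = model$dt_s)
  centers <- migration_time(model, sizes)
  heights <- amounts * model$amount_scale_fu
  if (model$stutter_fraction > 0 && length(sizes)) {
    st_sizes <- pmax(sizes - model$stutter_bp, 1)
    centers <- c(centers, migration_time(model, st_sizes))
    heights <- c(heights, model$stutter_fraction * heights)
  }
  centers <- c(migration_time(model, c(lower_marker_bp, upper_marker_bp)),
               centers)
  heights <- c(rep(model$marker_height_fu, 2), heights)
  fu <- gaussian_peaks(time_s, centers, heights, model$peak_sigma_s)
  if (model$noise_sd_fu > 0)
    fu <- fu + with_seed(seed, stats::rnorm(length(time_s), 0,
                                            model$noise_sd_fu))
  electropherogram(time_s, fu, well_kind = well_kind, label = label)
}

#' Simulate the sizing-ladder well
#'
#' One peak per ladder rung plus the two internal markers.
#'
#' @inheritParams simulate_trace
#' @param panel an \code{"str_panel"} supplying \code{ladder_sizes_bp} and the
#'   marker sizes.
#' @return An \code{"electropherogram"} with \code{well_kind = "ladder"}.
#' @export
simulate_ladder_trace <- function(panel, model, seed, label = "ladder") {
  if (length(panel$ladder_sizes_bp) == 0L)
    stop("panel has an empty ladder", call. = FALSE)
  frags <- data.frame(size_bp = panel$ladder_sizes_bp, amount = 1)
  tr <- simulate_trace(frags, model, seed,
                       lower_marker_bp = panel$lower_marker_bp,
                       upper_marker_bp = panel$upper_marker_bp,
                       well_kind = "ladder", label = label)
  tr
}

#' Simulate a sample well for one multiplex set of a profile
#'
#' Convenience wrapper: \code{\link{amplicons_for_profile}} followed by
#' \code{\link{simulate_trace}} with the panel's marker sizes.
#'
#' @inheritParams amplicons_for_profile
#' @inheritParams simulate_trace
#' @export
simulate_sample_trace <- function(panel, set_id, profile, model, seed,
                                  label = sprintf("%s/set%d", profile$sample,
                                                  set_id)) {
  frags <- amplicons_for_profile(panel, set_id, profile)
  simulate_trace(frags, model, seed,
                 lower_marker_bp = panel$lower_marker_bp,
                 upper_marker_bp = panel$upper_marker_bp,
                 well_kind = "sample", label = label)
}

#' Simulate a two-genome mixture well
#'
#' Fragment amounts of the two contributing profiles are scaled by
#' \code{1 - fraction_b} and \code{fraction_b}; at fraction 0 (or 1) the trace
#' is identical to the pure profile-A (or profile-B) well under the same seed.
#' The human sentinel locus amplifies only from a profile carrying human
#' alleles, so murine/human mixtures show both the murine and the human peak
#' in one well.
#'
#' @inheritParams amplicons_for_profile
#' @param profile_a,profile_b the two contributing \code{\link{str_profile}}s.
#' @param fraction_b mass fraction of profile B in [0, 1].
#' @inheritParams simulate_trace
#' @export
simulate_mixture <- function(panel, set_id, profile_a, profile_b, fraction_b,
                             model, seed,
                             label = sprintf("%s+%s/set%d", profile_a$sample,
                                             profile_b$sample, set_id)) {
  if (fraction_b < 0 || fraction_b > 1)
    stop("fraction_b must be in [0, 1]", call. = FALSE)
  fa <- amplicons_for_profile(panel, set_id, profile_a)
  fb <- amplicons_for_profile(panel, set_id, profile_b)
  fa$amount <- fa$amount * (1 - fraction_b)
  fb$amount <- fb$amount * fraction_b
  frags <- rbind(fa, fb)
  frags <- frags[frags$amount > 0, , drop = FALSE]
  simulate_trace(frags, model, seed,
                 lower_marker_bp = panel$lower_marker_bp,
                 upper_marker_bp = panel$upper_marker_bp,
                 well_kind = "sample", label = label)
}

#' Simulate all four multiplex wells of a sample
#'
#' @inheritParams simulate_sample_trace
#' @param seed base seed; well for set \eqn{k} uses \code{seed + k}.
#' @return Named list \code{set1..set4} of electropherograms.
#' @export
simulate_profile_wells <- function(panel, profile, model, seed) {
  wells <- lapply(1:4, function(s)
    simulate_sample_trace(panel, s, profile, model, seed + s))
  names(wells) <- paste0("set", 1:4)
  wells
}

#' Write / read an electropherogram as two-column delimited text
#'
#' The file holds commented header lines \code{# well_kind:} and
#' \code{# label:} followed by tab-separated \code{time_s} and \code{fu}
#' columns.
#'
#' @param trace an \code{"electropherogram"}.
#' @param path file path.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# well_kind: ", trace$well_kind),
               paste0("# label: ", trace$label),
               "time_s\tfu"), con)
  utils::write.table(data.frame(trace$time_s, trace$fu), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
}

#' @rdname write_trace
#' @return \code{read_trace} returns an \code{"electropherogram"}.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  hdr <- readLines(path, n = 10L)
  meta <- function(key, default) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(ln)) trimws(sub(paste0("^# ", key, ":"), "", ln[1])) else default
  }
  tab <- utils::read.delim(path, comment.char = "#")
  electropherogram(tab$time_s, tab$fu,
                   well_kind = meta("well_kind", "sample"),
                   label = meta("label", ""))
}
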