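#' STR locus descriptor
#'
#' Constructs the metadata record for a single short-tandem-repeat locus:
#' the amplicon of an allele with \eqn{r} motif copies is
#' \eqn{\mathrm{size} = \mathrm{flank\_offset\_bp} + \mathrm{repeat\_unit\_bp} \times r},
#' and during fragment length analysis a sized peak is attributed to the locus
#' whenever it falls inside the locus' predicted size range.
#'
#' @param name locus identifier, e.g. \code{"18-3"} or \code{"D8S1106"}.
#' @param species \code{"mouse"} or \code{"human"}.
#' @param repeat_unit_bp motif length in bp (4 for tetranucleotide repeats).
#' @param flank_offset_bp total non-repeat amplicon length in bp.
#' @param size_range_bp closed interval \code{c(lo, hi)} in bp; sized peaks in
#'   this interval are assigned to the locus.
#' @param multiplex_set integer in 1..4, the PCR set the locus is amplified in.
#' @param calibration_offset_bp per-locus systematic sizing offset in bp,
#'   subtracted from estimated sizes before repeat conversion. Default 0;
#'   intended for empirical calibration against a reference sample when the
#'   instrument shows a constant bias at a locus.
#' @return An object of class \code{"str_locus"}.
#' @examples
#' str_locus("18-3", "mouse", 4, 90, c(130, 198), 1)
#' @export
str_locus <- function(name, species = c("mouse", "human"), repeat_unit_bp = 4L,
                      flank_offset_bp, size_range_bp, multiplex_set,
                      calibration_offset_bp = 0) {
  species <- match.arg(species)
  loc <- structure(list(
    name = as.character(name),
    species = species,
    repeat_unit_bp = as.integer(repeat_unit_bp),
    flank_offset_bp = as.integer(flank_offset_bp),
    size_range_bp = as.numeric(size_range_bp),
    multiplex_set = as.integer(multiplex_set),
    calibration_offset_bp = as.numeric(calibration_offset_bp)
  ), class = "str_locus")
  validate_locus(loc)
  loc
}

validate_locus <- function(loc) {
  lo <- loc$size_range_bp[1]; hi <- loc$size_range_bp[2]
  if (loc$repeat_unit_bp < 1L)
    stop("locus '", loc$name, "': repeat_unit_bp must be >= 1", call. = FALSE)
  if (length(loc$size_range_bp) != 2L || !(lo < hi))
    stop("locus '", loc$name, "': size_range_bp must be c(lo, hi) with lo < hi",
         call. = FALSE)
  if (lo < 25 || hi > 1000)
    stop("locus '", loc$name, "': size range [", lo, ", ", hi,
         "] outside the 25-1000 bp chip sizing range", call. = FALSE)
  if (!(loc$flank_offset_bp < lo))
    stop("locus '", loc$name, "': flank_offset_bp (", loc$flank_offset_bp,
         ") must be smaller than the range lower bound (", lo, ")",
         call. = FALSE)
  # range endpoints must themselves be allele sizes, so that every integer
  # repeat count between them maps inside the closed interval
  if ((lo - loc$flank_offset_bp) %% loc$repeat_unit_bp != 0 ||
      (hi - loc$flank_offset_bp) %% loc$repeat_unit_bp != 0)
    stop("locus '", loc$name, "': size range endpoints are not of the form ",
         "flank_offset_bp + repeat_unit_bp * r for integer r", call. = FALSE)
  if (!(loc$multiplex_set %in% 1:4))
    stop("locus '", loc$name, "': multiplex_set must be in 1..4", call. = FALSE)
  invisible(loc)
}

#' @export
print.str_locus <- function(x, ...) {
  cat(sprintf("STR locus %s (%s), unit %d bp, offset %d bp, range [%g, %g] bp, set %d\n",
              x$name, x$species, x$repeat_unit_bp, x$flank_offset_bp,
              x$size_range_bp[1], x$size_range_bp[2], x$multiplex_set))
  invisible(x)
}

#' STR marker panel
#'
#' Bundles the loci of a multiplex STR assay with the chip's sizing ladder and
#' the two internal markers spiked into every well. Validation enforces the
#' multiplex design rules: size ranges within one PCR set must be pairwise
#' disjoint (a sized peak identifies its locus by size alone) and no set may
#' carry more than three loci per well.
#'
#' @param loci list of \code{\link{str_locus}} objects.
#' @param ladder_sizes_bp ascending fragment sizes (bp) of the sizing ladder.
#' @param lower_marker_bp,upper_marker_bp sizes (bp) of the lower and upper
#'   internal markers present in every well.
#' @return An object of class \code{"str_panel"}.
#' @seealso \code{\link{load_panel}} for reading a panel from a config file;
#'   \code{\link{default_panel}} for the shipped ten-marker murine panel.
#' @export
str_panel <- function(loci, ladder_sizes_bp, lower_marker_bp = 15,
                      upper_marker_bp = 1500) {
  panel <- structure(list(
    loci = loci,
    ladder_sizes_bp = as.numeric(ladder_sizes_bp),
    lower_marker_bp = as.numeric(lower_marker_bp),
    upper_marker_bp = as.numeric(upper_marker_bp)
  ), class = "str_panel")
  validate_panel(panel)
  panel
}

#' Validate a panel against the multiplex design rules
#'
#' @param panel an \code{"str_panel"} object.
#' @return The panel, invisibly; errors describe the offending loci.
#' @export
validate_panel <- function(panel) {
  if (length(panel$loci) == 0L)
    stop("panel contains no loci", call. = FALSE)
  for (loc in panel$loci) validate_locus(loc)
  nm <- vapply(panel$loci, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("duplicate locus names: ", paste(nm[duplicated(nm)], collapse = ", "),
         call. = FALSE)
  sets <- vapply(panel$loci, `[[`, integer(1), "multiplex_set")
  for (s in sort(unique(sets))) {
    idx <- which(sets == s)
    if (length(idx) > 3L)
      stop("multiplex set ", s, " has ", length(idx),
           " loci (at most 3 markers fit in one well): ",
           paste(nm[idx], collapse = ", "), call. = FALSE)
    if (length(idx) > 1L) {
      rng <- t(vapply(panel$loci[idx], `[[`, numeric(2), "size_range_bp"))
      for (i in seq_len(length(idx) - 1L)) for (j in (i + 1L):length(idx)) {
        if (rng[i, 1] <= rng[j, 2] && rng[j, 1] <= rng[i, 2])
          stop("size ranges of loci '", nm[idx[i]], "' and '", nm[idx[j]],
               "' overlap within multiplex set ", s,
               "; size alone must identify the locus", call. = FALSE)
      }
    }
  }
  lad <- panel$ladder_sizes_bp
  if (length(lad) < 2L || is.unsorted(lad, strictly = TRUE))
    stop("ladder_sizes_bp must be >= 2 strictly ascending sizes", call. = FALSE)
  if (panel$lower_marker_bp >= min(lad) || panel$upper_marker_bp <= max(lad))
    stop("internal markers must bracket the ladder sizes", call. = FALSE)
  invisible(panel)
}

#' @export
print.str_panel <- function(x, ...) {
  nm <- vapply(x$loci, `[[`, character(1), "name")
  sp <- vapply(x$loci, `[[`, character(1), "species")
  cat(sprintf("STR panel: %d loci (%d mouse, %d human), amplicons %g-%g bp\n",
              length(x$loci), sum(sp == "mouse"), sum(sp == "human"),
              min(vapply(x$loci, function(l) l$size_range_bp[1], numeric(1))),
              max(vapply(x$loci, function(l) l$size_range_bp[2], numeric(1)))))
  for (s in 1:4) {
    in_s <- nm[vapply(x$loci, `[[`, integer(1), "multiplex_set") == s]
    if (length(in_s)) cat("  set ", s, ": ", paste(in_s, collapse = ", "), "\n",
                          sep = "")
  }
  invisible(x)
}

#' Load an STR panel from a YAML config file
#'
#' The config carries \code{ladder_sizes_bp}, \code{lower_marker_bp},
#' \code{upper_marker_bp} and a \code{loci} list whose records have the fields
#' of \code{\link{str_locus}}. The shipped default config is
#' \code{system.file("extdata", "panel_default.yaml", package = "strchip")}.
#'
#' @param config_path path to the YAML panel definition.
#' @return A validated \code{"str_panel"}.
#' @examples
#' panel <- load_panel(system.file("extdata", "panel_default.yaml",
#'                                 package = "strchip"))
#' panel
#' @export
load_panel <- function(config_path) {
  if (!file.exists(config_path))
    stop("panel config file not found: ", config_path, call. = FALSE)
  cfg <- yaml::read_yaml(config_path)
  for (field in c("loci", "ladder_sizes_bp", "lower_marker_bp",
                  "upper_marker_bp"))
    if (is.null(cfg[[field]]))
      stop("panel config is missing field '", field, "'", call. = FALSE)
  if (length(cfg$loci) == 0L)
    stop("panel config defines no loci", call. = FALSE)
  loci <- lapply(cfg$loci, function(rec) {
    need <- c("name", "species", "flank_offset_bp", "size_range_bp",
              "multiplex_set")
    miss <- need[!need %in% names(rec)]
    if (length(miss))
      stop("locus record ", if (!is.null(rec$name)) paste0("'", rec$name, "' "),
           "is missing field(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    str_locus(rec$name, rec$species,
              repeat_unit_bp = rec$repeat_unit_bp %||% 4L,
              flank_offset_bp = rec$flank_offset_bp,
              size_range_bp = unlist(rec$size_range_bp),
              multiplex_set = rec$multiplex_set,
              calibration_offset_bp = rec$calibration_offset_bp %||% 0)
  })
  str_panel(loci, cfg$ladder_sizes_bp, cfg$lower_marker_bp,
            cfg$upper_marker_bp)
}

#' Default ten-marker murine authentication panel
#'
#' Nine tetranucleotide murine loci (18-3, 4-2, 6-7, 9-2, 15-3, 6-4, 12-1,
#' 5-5, X-1) plus the human sentinel locus D8S1106 used for interspecies
#' contamination detection, distributed over four multiplex sets with
#' amplicons spanning 130-515 bp, together with an 11-rung 25-1000 bp sizing
#' ladder and internal markers at 15 and 1500 bp.
#'
#' @return A validated \code{"str_panel"}.
#' @export
default_panel <- function() {
  load_panel(system.file("extdata", "panel_default.yaml", package = "strchip",
                         mustWork = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

panel_locus <- function(panel, name) {
  nm <- vapply(panel$loci, `[[`, character(1), "name")
  i <- match(name, nm)
  if (is.na(i)) stop("no locus named '", name, "' in panel", call. = FALSE)
  panel$loci[[i]]
}

panel_locus_names <- function(panel, species = NULL) {
  keep <- if (is.null(species)) rep(TRUE, length(panel$loci))
          else vapply(panel$loci, `[[`, character(1), "species") == species
  vapply(panel$loci[keep], `[[`, character(1), "name")
}

set_loci <- function(panel, set_id) {
  if (!(length(set_id) == 1L && set_id %in% 1:4))
    stop("set_id must be a single integer in 1..4", call. = FALSE)
  panel$loci[vapply(panel$loci, `[[`, integer(1), "multiplex_set") == set_id]
}

#' Predicted amplicon size of an allele
#'
#' @param locus an \code{\link{str_locus}}.
#' @param repeats integer repeat count(s), >= 1.
#' @return Amplicon size(s) in bp:
#'   \code{flank_offset_bp + repeat_unit_bp * repeats}.
#' @examples
#' L <- str_locus("ex", "mouse", 4, 96, c(120, 200), 1)
#' predicted_size(L, 16)  # 160
#' @export
predicted_size <- function(locus, repeats) {
  if (any(repeats < 1) || any(repeats != round(repeats)))
    stop("repeats must be positive integers", call. = FALSE)
  locus$flank_offset_bp + locus$repeat_unit_bp * repeats
}

#' Repeat count from a measured fragment size
#'
#' Inverts \code{\link{predicted_size}} by nearest-allele binning: the repeat
#' count is the nearest integer of
#' \code{(size - flank_offset_bp - calibration_offset_bp) / repeat_unit_bp},
#' and the residual is the signed distance (bp) from the predicted allele
#' size, bounded by half a repeat unit.
#'
#' @param locus an \code{\link{str_locus}}.
#' @param size measured fragment size in bp.
#' @param range_tol_bp slack (bp) beyond the locus size range within which a
#'   size is still converted; default half a repeat unit.
#' @return A list with \code{repeats} (integer, \code{NA} for a no-call when
#'   the size falls outside the extended range) and \code{residual_bp}.
#' @export
repeats_from_size <- function(locus, size,
                              range_tol_bp = locus$repeat_unit_bp / 2) {
  size_adj <- size - locus$calibration_offset_bp
  if (size < locus$size_range_bp[1] - range_tol_bp ||
      size > locus$size_range_bp[2] + range_tol_bp)
    return(list(repeats = NA_integer_, residual_bp = NA_real_))
  r <- as.integer(round((size_adj - locus$flank_offset_bp) /
                          locus$repeat_unit_bp))
  r <- max(r, 1L)
  list(repeats = r, residual_bp = size_adj - predicted_size(locus, r))
}

#' Locus identification by fragment size within a multiplex set
#'
#' Returns the unique locus of the multiplex set whose closed size range
#' contains \code{size} (boundary sizes belong to the locus), or \code{NULL}
#' when the size lies outside all ranges of the set. Uniqueness is guaranteed
#' by the panel's within-set disjointness invariant.
#'
#' @param panel an \code{"str_panel"}.
#' @param set_id multiplex set, integer in 1..4.
#' @param size fragment size in bp.
#' @return An \code{\link{str_locus}} or \code{NULL}.
#' @export
locus_for_size <- function(panel, set_id, size) {
  for (loc in set_loci(panel, set_id))
    if (size >= loc$size_range_bp[1] && size <= loc$size_range_bp[2])
      return(loc)
  NULL
}
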