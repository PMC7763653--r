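#' Attribute sized peaks to the loci of a multiplex set
#'
#' Each in-range peak is attached to the unique locus of the set whose closed
#' predicted size range contains its estimated size (within-set disjointness
#' makes the assignment unambiguous); peaks matching no range are returned
#' separately rather than raising an error.
#'
#' @param sized_peaks a \code{"sized_peaks"} data.frame from
#'   \code{\link{size_peaks}}.
#' @param panel an \code{"str_panel"}.
#' @param set_id multiplex set, 1..4.
#' @return list with \code{assigned} (named list: locus -> sized-peak rows)
#'   and \code{unassigned} (sized-peak rows).
#' @export
assign_loci <- function(sized_peaks, panel, set_id) {
  loci <- set_loci(panel, set_id)
  assigned <- stats::setNames(vector("list", length(loci)),
                              vapply(loci, `[[`, character(1), "name"))
  hit <- rep(FALSE, nrow(sized_peaks))
  for (loc in loci) {
    in_rng <- sized_peaks$in_sizing_range &
      sized_peaks$size_bp >= loc$size_range_bp[1] &
      sized_peaks$size_bp <= loc$size_range_bp[2]
    assigned[[loc$name]] <- sized_peaks[in_rng, , drop = FALSE]
    hit <- hit | in_rng
  }
  list(assigned = assigned,
       unassigned = sized_peaks[!hit, , drop = FALSE])
}

#' Call 1-2 alleles at one locus from its assigned peaks
#'
#' The tallest peak defines the first allele. A further peak becomes the
#' second allele when its height reaches \code{het_ratio} of the tallest and
#' it is not explained as a stutter artifact, i.e. it does not sit one repeat
#' unit below a taller peak at less than \code{stutter_ratio} of that peak's
#' height. When more than two peaks survive both filters, the top two are
#' called and flagged \code{extra_allele} - the downstream contamination
#' check consumes that flag. Repeat counts come from
#' \code{\link{repeats_from_size}}; calls are invariant to peak order and to
#' uniform scaling of all heights.
#'
#' @param locus_peaks sized-peak rows assigned to the locus.
#' @param locus the \code{\link{str_locus}}.
#' @param het_ratio minimum relative height of a second allele.
#' @param stutter_ratio maximum relative height at which a one-unit-shorter
#'   neighbour is treated as stutter.
#' @return data.frame of class \code{"allele_calls"}: \code{locus},
#'   \code{repeats}, \code{size_bp}, \code{height_fu}, \code{residual_bp},
#'   \code{flags} (comma-joined), 0-2 rows.
#' @export
call_alleles <- function(locus_peaks, locus, het_ratio = 0.4,
                         stutter_ratio = 0.3) {
  empty <- structure(data.frame(locus = character(0), repeats = integer(0),
                                size_bp = numeric(0), height_fu = numeric(0),
                                residual_bp = numeric(0),
                                flags = character(0)),
                     class = c("allele_calls", "data.frame"))
  if (is.null(locus_peaks) || nrow(locus_peaks) == 0L) return(empty)
  pk <- locus_peaks[order(-locus_peaks$height_fu, locus_peaks$size_bp), ,
                    drop = FALSE]
  unit <- locus$repeat_unit_bp
  # stutter filter: shorter-by-one-unit neighbour of a taller peak
  is_stutter <- vapply(seq_len(nrow(pk)), function(i) {
    any(pk$height_fu > pk$height_fu[i] / stutter_ratio &
          abs(pk$size_bp - (pk$size_bp[i] + unit)) <= unit / 2)
  }, logical(1))
  stutter_seen <- any(is_stutter)
  surv <- pk[!is_stutter, , drop = FALSE]
  if (nrow(surv) == 0L) return(empty)
  keep <- surv$height_fu >= het_ratio * surv$height_fu[1]
  surv <- surv[keep, , drop = FALSE]
  extra <- nrow(surv) > 2L
  surv <- surv[seq_len(min(2L, nrow(surv))), , drop = FALSE]
  calls <- lapply(seq_len(nrow(surv)), function(i) {
    conv <- repeats_from_size(locus, surv$size_bp[i])
    if (is.na(conv$repeats)) return(NULL)
    flags <- c(if (extra) "extra_allele",
               if (stutter_seen) "stutter_filtered_neighbor",
               if (!surv$in_sizing_range[i]) "off_scale")
    data.frame(locus = locus$name, repeats = conv$repeats,
               size_bp = surv$size_bp[i], height_fu = surv$height_fu[i],
               residual_bp = conv$residual_bp,
               flags = paste(flags, collapse = ","))
  })
  calls <- calls[!vapply(calls, is.null, logical(1))]
  if (!length(calls)) return(empty)
  out <- do.call(rbind, calls)
  out <- out[order(out$repeats), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("allele_calls", "data.frame"))
}

#' Call all loci of one multiplex well
#'
#' \code{\link{assign_loci}} followed by \code{\link{call_alleles}} per locus.
#'
#' @inheritParams assign_loci
#' @inheritParams call_alleles
#' @return Named list: locus name -> \code{"allele_calls"} data.frame.
#' @export
call_set <- function(sized_peaks, panel, set_id, het_ratio = 0.4,
                     stutter_ratio = 0.3) {
  asg <- assign_loci(sized_peaks, panel, set_id)
  out <- lapply(names(asg$assigned), function(nm)
    call_alleles(asg$assigned[[nm]], panel_locus(panel, nm),
                 het_ratio = het_ratio, stutter_ratio = stutter_ratio))
  stats::setNames(out, names(asg$assigned))
}

#' Assemble a sample's STR profile from per-set allele calls
#'
#' Merges the call maps of the four multiplex wells into one profile. Murine
#' loci without calls are recorded as explicit no-calls; alleles of the human
#' sentinel locus are stored as the species flag, never as a murine genotype.
#' A locus appearing in more than one set's calls is an assay design error.
#'
#' @param set_calls list of per-set call maps (as from \code{\link{call_set}}).
#' @param panel an \code{"str_panel"}.
#' @param sample_label label for the assembled profile.
#' @return An \code{\link{str_profile}}.
#' @export
build_profile <- function(set_calls, panel, sample_label) {
  murine <- panel_locus_names(panel, "mouse")
  human <- panel_locus_names(panel, "human")
  calls <- stats::setNames(rep(list(integer(0)), length(murine)), murine)
  flags <- list()
  human_alleles <- integer(0)
  seen <- character(0)
  for (m in set_calls) for (nm in names(m)) {
    cc <- m[[nm]]
    if (is.null(cc) || nrow(cc) == 0L) next
    if (nm %in% seen)
      stop("locus '", nm, "' called in more than one multiplex set",
           call. = FALSE)
    seen <- c(seen, nm)
    fl <- setdiff(unique(unlist(strsplit(cc$flags, ","))), "")
    if (length(fl)) flags[[nm]] <- fl
    if (nm %in% human) human_alleles <- cc$repeats
    else calls[[nm]] <- cc$repeats
  }
  str_profile(sample_label, calls, human_alleles = human_alleles,
              locus_flags = flags)
}

#' Full trace-to-profile pipeline for one sample
#'
#' Fits the ladder calibration, sizes each multiplex well, calls alleles and
#' assembles the profile.
#'
#' @param ladder_trace ladder-well \code{"electropherogram"}.
#' @param set_traces named or positional list of four sample-well traces, one
#'   per multiplex set (in set order).
#' @param panel an \code{"str_panel"}.
#' @param sample_label profile label.
#' @inheritParams call_alleles
#' @param min_snr detection threshold, see \code{\link{detect_peaks}}.
#' @return An \code{\link{str_profile}}.
#' @export
profile_from_traces <- function(ladder_trace, set_traces, panel, sample_label,
                                het_ratio = 0.4, stutter_ratio = 0.3,
                                min_snr = 5) {
  cal <- fit_calibration(ladder_trace, panel$ladder_sizes_bp,
                         min_snr = min_snr)
  set_calls <- lapply(seq_along(set_traces), function(s) {
    sp <- size_peaks(set_traces[[s]], cal, min_snr = min_snr)
    call_set(sp, panel, s, het_ratio = het_ratio,
             stutter_ratio = stutter_ratio)
  })
  build_profile(set_calls, panel, sample_label)
}
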