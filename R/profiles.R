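#' STR profile of one sample
#'
#' A profile maps each murine locus to a multiset of 1-2 repeat counts
#' (homozygous or single-detectable-allele loci carry one value, printed
#' duplicates such as "19, 19" are normalized to one value on construction);
#' a locus with an empty multiset is an explicit no-call. Alleles of the human
#' sentinel locus are held separately: they flag the species of origin and
#' never enter murine genotypes or match scores.
#'
#' @param sample sample label.
#' @param calls named list, murine locus name -> integer vector of repeat
#'   counts (\code{integer(0)} for a no-call).
#' @param human_alleles integer vector of human-locus repeat counts
#'   (empty when no human material was detected).
#' @param locus_flags named list, locus name -> character vector of calling
#'   flags (e.g. \code{"extra_allele"}, \code{"stutter_filtered_neighbor"}).
#' @return An object of class \code{"str_profile"}.
#' @export
str_profile <- function(sample, calls, human_alleles = integer(0),
                        locus_flags = list()) {
  stopifnot(is.list(calls))
  if (length(calls) && is.null(names(calls)))
    stop("calls must be a named list (locus -> repeats)", call. = FALSE)
  calls <- lapply(calls, function(a) sort(unique(as.integer(a))))
  bad <- names(calls)[vapply(calls, length, integer(1)) > 2L]
  if (length(bad))
    stop("more than 2 alleles stored at locus ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(sample = as.character(sample), calls = calls,
                 human_alleles = sort(unique(as.integer(human_alleles))),
                 locus_flags = locus_flags),
            class = "str_profile")
}

#' @export
print.str_profile <- function(x, ...) {
  cat("STR profile '", x$sample, "'\n", sep = "")
  for (nm in names(x$calls)) {
    a <- x$calls[[nm]]
    cat(sprintf("  %-8s %s", nm,
                if (length(a)) paste(a, collapse = ", ") else "no-call"))
    fl <- x$locus_flags[[nm]]
    if (length(fl)) cat("  [", paste(fl, collapse = ","), "]", sep = "")
    cat("\n")
  }
  if (length(x$human_alleles))
    cat("  human locus alleles: ", paste(x$human_alleles, collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Murine loci of a profile that carry at least one called allele
#' @param profile an \code{"str_profile"}.
#' @return Character vector of locus names.
#' @export
called_loci <- function(profile) {
  names(profile$calls)[vapply(profile$calls, length, integer(1)) > 0L]
}

#' Read STR profiles from a delimited table
#'
#' The table layout mirrors published profile tables: one row per sample, a
#' \code{sample} column, then one column per locus with comma-separated repeat
#' counts ("15, 18"), a single count, or an empty cell / \code{"-"} for a
#' no-call. A \code{D8S1106} column, when present, is read as human-locus
#' alleles.
#'
#' @param path path to a tab-separated profile table.
#' @return A named list of \code{\link{str_profile}} objects.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path))
    stop("profile file not found: ", path, call. = FALSE)
  # comment.char must stay disabled: sample labels may begin with '#'
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character", comment.char = "")
  if (!"sample" %in% names(tab))
    stop("profile table needs a 'sample' column", call. = FALSE)
  loci <- setdiff(names(tab), "sample")
  profs <- lapply(seq_len(nrow(tab)), function(i) {
    calls <- list()
    human <- integer(0)
    for (loc in loci) {
      cell <- trimws(tab[i, loc])
      reps <- if (nzchar(cell) && cell != "-")
        as.integer(trimws(strsplit(cell, ",")[[1]])) else integer(0)
      if (identical(loc, "D8S1106")) human <- reps else calls[[loc]] <- reps
    }
    str_profile(tab$sample[i], calls, human_alleles = human)
  })
  names(profs) <- tab$sample
  profs
}

#' Write STR profiles as a delimited table
#'
#' Inverse of \code{\link{read_profiles}}; the column order follows
#' \code{loci}, defaulting to the union of loci over the profiles.
#'
#' @param profiles list of \code{\link{str_profile}} objects.
#' @param path output path (tab-separated).
#' @param loci locus column order.
#' @export
write_profiles <- function(profiles, path,
                           loci = unique(unlist(lapply(profiles, function(p)
                             c(names(p$calls),
                               if (length(p$human_alleles)) "D8S1106"))))) {
  rows <- lapply(profiles, function(p) {
    cells <- vapply(loci, function(loc) {
      a <- if (identical(loc, "D8S1106")) p$human_alleles else p$calls[[loc]]
      if (length(a)) paste(a, collapse = ", ") else ""
    }, character(1))
    c(sample = p$sample, cells)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

fixture_profiles <- function(file) {
  read_profiles(system.file("extdata", file, package = "strchip",
                            mustWork = TRUE))
}

#' Reference STR profiles of the three HoxB8-FL progenitor lines
#' @return Named list of three \code{\link{str_profile}} objects
#'   (#1_HoxB8FL wild-type, #2_HoxB8FL Imu-HA-Bcl6, #3_HoxB8FL Cxcr4-WHIM).
#' @export
hoxb8_profiles <- function() fixture_profiles("profiles_hoxb8.tsv")

#' Reference STR profiles of the three murine PDAC lines
#' @return Named list of three \code{\link{str_profile}} objects
#'   (mPDAC06, mPDAC09, mPDAC95).
#' @export
mpdac_profiles <- function() fixture_profiles("profiles_mpdac.tsv")

#' Synthetic human MM.1S profile (human sentinel locus only)
#'
#' The published record does not include the MM.1S repeat count at the human
#' sentinel locus; this fixture assigns a plausible synthetic allele so that
#' interspecies mixture experiments can be simulated. Murine loci are all
#' no-calls, as expected for a pure human sample.
#' @return An \code{\link{str_profile}}.
#' @export
mm1s_profile <- function() fixture_profiles("profile_mm1s_synthetic.tsv")[[1]]

#' All six murine reference profiles (HoxB8-FL + PDAC)
#' @return Named list of six \code{\link{str_profile}} objects.
#' @export
reference_profiles <- function() c(hoxb8_profiles(), mpdac_profiles())
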