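#' Match score between two STR profiles
#'
#' Shared-allele scoring in the style of the ANSI/ATCC cell line
#' authentication standard, computed over the murine loci called in both
#' profiles (the human sentinel locus never enters the score). Per common
#' locus the shared count is the multiset intersection of the two allele
#' sets. Algorithms: \code{tanabe} = 2*shared / (n_query + n_ref)
#' (symmetric), \code{masters_query} = shared / n_query,
#' \code{masters_ref} = shared / n_ref.
#'
#' @param query,reference \code{\link{str_profile}} objects.
#' @param algorithm scoring variant.
#' @param match_threshold score at or above which the verdict is
#'   \code{"match"}.
#' @param related_threshold score at or above which the verdict is
#'   \code{"related"}.
#' @return An object of class \code{"comparison_result"}: labels, per-locus
#'   shared counts, \code{n_shared}, \code{n_query_alleles},
#'   \code{n_ref_alleles}, \code{score}, \code{algorithm}, \code{verdict}.
#' @examples
#' p <- hoxb8_profiles()
#' match_score(p[["#1_HoxB8FL"]], p[["#3_HoxB8FL"]])
#' @export
match_score <- function(query, reference,
                        algorithm = c("tanabe", "masters_query",
                                      "masters_ref"),
                        match_threshold = 0.8, related_threshold = 0.55) {
  algorithm <- match.arg(algorithm)
  common <- intersect(called_loci(query), called_loci(reference))
  if (length(common) == 0L)
    stop("profiles '", query$sample, "' and '", reference$sample,
         "' share no called loci", call. = FALSE)
  shared <- vapply(common, function(nm) {
    q <- query$calls[[nm]]; r <- reference$calls[[nm]]
    sum(pmin(table(q)[as.character(intersect(q, r))],
             table(r)[as.character(intersect(q, r))]))
  }, numeric(1))
  nq <- sum(vapply(common, function(nm) length(query$calls[[nm]]),
                   integer(1)))
  nr <- sum(vapply(common, function(nm) length(reference$calls[[nm]]),
                   integer(1)))
  ns <- sum(shared)
  score <- switch(algorithm,
                  tanabe = 2 * ns / (nq + nr),
                  masters_query = ns / nq,
                  masters_ref = ns / nr)
  verdict <- if (score >= match_threshold) "match"
             else if (score >= related_threshold) "related" else "mismatch"
  structure(list(query = query$sample, reference = reference$sample,
                 shared_per_locus = shared, n_shared = ns,
                 n_query_alleles = nq, n_ref_alleles = nr, score = score,
                 algorithm = algorithm, verdict = verdict,
                 match_threshold = match_threshold,
                 related_threshold = related_threshold),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s vs %s: %d shared / (%d + %d) alleles, %s score %.3f -> %s\n",
              x$query, x$reference, x$n_shared, x$n_query_alleles,
              x$n_ref_alleles, x$algorithm, x$score, x$verdict))
  cat(sprintf("  (thresholds: match >= %.2f, related >= %.2f)\n",
              x$match_threshold, x$related_threshold))
  invisible(x)
}

#' Authenticate a query profile against a reference database
#'
#' Scores the query against every database profile and ranks the results by
#' descending score, ties broken by reference label.
#'
#' @inheritParams match_score
#' @param db list of reference \code{\link{str_profile}} objects.
#' @return list of class \code{"authentication_result"}: \code{results}
#'   (ranked \code{"comparison_result"}s), \code{best} (top hit),
#'   \code{verdict} (the top hit's verdict).
#' @export
authenticate_against_db <- function(query, db,
                                    algorithm = "tanabe",
                                    match_threshold = 0.8,
                                    related_threshold = 0.55) {
  if (length(db) == 0L)
    stop("reference database is empty", call. = FALSE)
  results <- lapply(db, function(ref)
    match_score(query, ref, algorithm = algorithm,
                match_threshold = match_threshold,
                related_threshold = related_threshold))
  ord <- order(-vapply(results, `[[`, numeric(1), "score"),
               vapply(results, `[[`, character(1), "reference"))
  results <- results[ord]
  structure(list(results = results, best = results[[1]],
                 verdict = results[[1]]$verdict),
            class = "authentication_result")
}

#' @export
print.authentication_result <- function(x, ...) {
  cat("Authentication of '", x$results[[1]]$query, "' against ",
      length(x$results), " reference profiles:\n", sep = "")
  for (r in x$results)
    cat(sprintf("  %-12s score %.3f  %s\n", r$reference, r$score, r$verdict))
  invisible(x)
}

#' Passage-stability check over replicate profiles of one line
#'
#' Compares all profile pairs (e.g. early passage, late passage,
#' post-cryopreservation). The line is stable when every pair is identical at
#' every locus called in both; discordant loci are listed.
#'
#' @param profiles list of >= 2 \code{\link{str_profile}} objects of the same
#'   line.
#' @return list of class \code{"stability_report"}: \code{stable},
#'   \code{discordant_loci}, \code{n_profiles}.
#' @export
check_passage_stability <- function(profiles) {
  if (length(profiles) < 2L)
    stop("stability check needs at least two profiles", call. = FALSE)
  discordant <- character(0)
  n <- length(profiles)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    common <- intersect(called_loci(profiles[[i]]),
                        called_loci(profiles[[j]]))
    for (nm in common)
      if (!identical(profiles[[i]]$calls[[nm]], profiles[[j]]$calls[[nm]]))
        discordant <- union(discordant, nm)
  }
  structure(list(stable = length(discordant) == 0L,
                 discordant_loci = discordant, n_profiles = n),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Passage stability over %d profiles: %s\n", x$n_profiles,
              if (x$stable) "stable" else "UNSTABLE"))
  if (!x$stable)
    cat("  discordant loci: ", paste(x$discordant_loci, collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

contamination_report <- function(interspecies_flag = FALSE,
                                 intraspecies_flag = FALSE,
                                 supporting_loci = character(0),
                                 species = NA_character_) {
  structure(list(interspecies_flag = interspecies_flag,
                 intraspecies_flag = intraspecies_flag,
                 supporting_loci = supporting_loci, species = species),
            class = "contamination_report")
}

#' @export
print.contamination_report <- function(x, ...) {
  cat("Contamination report: species = ", x$species,
      "; interspecies flag = ", x$interspecies_flag,
      "; intraspecies flag = ", x$intraspecies_flag, "\n", sep = "")
  if (length(x$supporting_loci))
    cat("  supporting loci: ", paste(x$supporting_loci, collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Interspecies (human/murine) contamination check
#'
#' Flags human contamination of a murine sample when the human sentinel locus
#' is detected alongside at least one called murine locus. A sample showing
#' only the human locus is reported as a pure human sample (species
#' \code{"human"}), not as contaminated. Accepts either a built profile or a
#' \code{"sized_peaks"} table from the sentinel-carrying multiplex well
#' (default set 2), in which case sentinel/murine presence is judged from the
#' peak sizes directly.
#'
#' @param x an \code{\link{str_profile}} or a \code{"sized_peaks"} data.frame.
#' @param panel an \code{"str_panel"}.
#' @param set_id multiplex set of \code{x} when it is a peak table.
#' @return A \code{"contamination_report"}.
#' @export
detect_interspecies <- function(x, panel, set_id = 2L) {
  if (inherits(x, "str_profile")) {
    human <- length(x$human_alleles) > 0L
    murine <- length(called_loci(x)) > 0L
  } else {
    human <- FALSE; murine <- FALSE
    for (i in seq_len(nrow(x))) {
      loc <- locus_for_size(panel, set_id, x$size_bp[i])
      if (is.null(loc)) next
      if (loc$species == "human") human <- TRUE else murine <- TRUE
    }
  }
  human_loci <- panel_locus_names(panel, "human")
  if (human && murine)
    contamination_report(interspecies_flag = TRUE,
                         supporting_loci = human_loci, species = "mouse")
  else if (human)
    contamination_report(species = "human")
  else if (murine)
    contamination_report(species = "mouse")
  else
    contamination_report(species = NA_character_)
}

#' Intraspecies (murine/murine) contamination check
#'
#' Without a reference, a locus supports contamination when its calling left
#' an \code{extra_allele} flag (more than two surviving peaks). When the
#' sample carries an identity claim, pass the claimed line's reference
#' profile: a locus then also counts when the called multiset contains
#' alleles absent from the reference, which detects mixtures of two
#' single-allele (inbred-derived) lines that never exceed two peaks per
#' locus. The flag is raised when at least \code{min_extra_loci} loci
#' support it.
#'
#' @param profile a murine \code{\link{str_profile}}.
#' @param min_extra_loci minimum number of supporting loci.
#' @param reference optional claimed-identity \code{\link{str_profile}}.
#' @return A \code{"contamination_report"}.
#' @export
detect_intraspecies <- function(profile, min_extra_loci = 2L,
                                reference = NULL) {
  support <- character(0)
  for (nm in called_loci(profile)) {
    extra <- "extra_allele" %in% profile$locus_flags[[nm]]
    if (!extra && !is.null(reference)) {
      ref <- reference$calls[[nm]]
      if (!is.null(ref) && length(ref) &&
          length(setdiff(profile$calls[[nm]], ref)) > 0L)
        extra <- TRUE
    }
    if (extra) support <- c(support, nm)
  }
  contamination_report(intraspecies_flag = length(support) >= min_extra_loci,
                       supporting_loci = support, species = "mouse")
}
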