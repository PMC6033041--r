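#' Antigen-contacting residues of a bound complex
#'
#' A binder residue contacts the antigen iff the minimum distance
#' between its heavy atoms and any antigen heavy atom is strictly below
#' the cutoff (5 Angstrom by default).
#'
#' @param complex A bound \code{complex_record}.
#' @param cutoff Contact distance cutoff in Angstrom (default 5.0;
#'   strict \code{<}).
#' @return A \code{contact_set}: data frame with \code{res_index},
#'   \code{min_dist}, \code{contact}; the contact residue indices are
#'   in attribute \code{"contacts"}.
#' @export
contact_residues <- function(complex, cutoff = 5.0) {
  stopifnot(inherits(complex, "complex_record"))
  if (complex$state != "bound") {
    stop("contact detection requires a bound complex (state is '",
         complex$state, "')")
  }
  ba <- complex$binder$atoms
  ag <- complex$antigen
  if (nrow(ag) == 0L) stop("bound complex has no antigen atoms")
  bxyz <- as.matrix(ba[, c("x", "y", "z")])
  axyz <- as.matrix(ag[, c("x", "y", "z")])
  # squared distances binder-atoms x antigen-atoms
  d2 <- outer(rowSums(bxyz^2), rowSums(axyz^2), "+") -
    2 * tcrossprod(bxyz, axyz)
  atom_min <- sqrt(pmax(apply(d2, 1, min), 0))
  n_res <- length(complex$binder$aa)
  min_dist <- rep(Inf, n_res)
  agg <- tapply(atom_min, ba$res_index, min)
  min_dist[as.integer(names(agg))] <- agg
  contact <- min_dist < cutoff
  out <- data.frame(res_index = seq_len(n_res), min_dist = min_dist,
                    contact = contact)
  attr(out, "contacts") <- which(contact)
  class(out) <- c("contact_set", "data.frame")
  out
}

#' Mean and spread of per-structure contact counts
#'
#' @param records List of \code{complex_record}s; apo records are
#'   skipped.
#' @param cutoff Contact cutoff in Angstrom (default 5.0).
#' @return List with \code{counts} (named per-structure counts over
#'   bound records), \code{mean}, \code{sd}, \code{n_structures}.
#' @export
contact_count_stats <- function(records, cutoff = 5.0) {
  bound <- Filter(function(r) r$state == "bound", records)
  if (length(bound) == 0L) stop("no bound records")
  counts <- vapply(bound, function(r) {
    length(attr(contact_residues(r, cutoff), "contacts"))
  }, integer(1))
  names(counts) <- vapply(bound, `[[`, character(1), "id")
  list(counts = counts, mean = mean(counts), sd = stats::sd(counts),
       n_structures = length(counts))
}

#' Per-position antigen-contact propensity
#'
#' Maps each structure's contact residues to scheme positions through
#' its numbering table and reports, per position, the fraction of bound
#' structures whose residue there contacts the antigen. The default
#' denominator is the number of bound structures; the per-position
#' ungapped denominator is also reported. Residues beyond the numbering
#' table (e.g. expression tags) are excluded from the profile (a
#' message reports how many).
#'
#' @param records List of \code{complex_record}s (apo records skipped).
#' @param numbering List of \code{numbered_sequence}s, parallel to
#'   \code{records}.
#' @param scheme_length Total number of scheme positions.
#' @param cutoff Contact cutoff in Angstrom (default 5.0).
#' @return A data frame (\code{propensity_profile}) with columns
#'   \code{position}, \code{n_contact}, \code{n_bound},
#'   \code{n_ungapped}, \code{propensity} (= n_contact / n_bound) and
#'   \code{propensity_ungapped} (= n_contact / n_ungapped).
#' @export
contact_propensity <- function(records, numbering, scheme_length,
                               cutoff = 5.0) {
  stopifnot(length(records) == length(numbering))
  bound <- which(vapply(records, function(r) r$state == "bound", logical(1)))
  if (length(bound) == 0L) stop("no bound records")
  n_contact <- integer(scheme_length)
  n_ungapped <- integer(scheme_length)
  n_unmapped <- 0L
  for (i in bound) {
    num <- numbering[[i]]
    cs <- contact_residues(records[[i]], cutoff)
    contacts <- attr(cs, "contacts")
    mapped <- contacts[contacts <= length(num$positions)]
    n_unmapped <- n_unmapped + (length(contacts) - length(mapped))
    n_contact[num$positions[mapped]] <-
      n_contact[num$positions[mapped]] + 1L
    n_ungapped[num$positions] <- n_ungapped[num$positions] + 1L
  }
  if (n_unmapped > 0L) {
    message("contact_propensity: ", n_unmapped,
            " contact residue(s) beyond the numbering tables were ",
            "excluded from the profile")
  }
  out <- data.frame(
    position = seq_len(scheme_length),
    n_contact = n_contact,
    n_bound = length(bound),
    n_ungapped = n_ungapped,
    propensity = n_contact / length(bound),
    propensity_ungapped = ifelse(n_ungapped > 0L, n_contact / n_ungapped,
                                 NA_real_)
  )
  class(out) <- c("propensity_profile", "data.frame")
  out
}

#' Paratope positions from a propensity profile
#'
#' Positions whose contact propensity strictly exceeds the threshold
#' (default 0.10, i.e. contacting the antigen in more than 10% of
#' structures).
#'
#' @param profile A \code{propensity_profile} from
#'   [contact_propensity()].
#' @param threshold Propensity threshold (default 0.10; strict
#'   \code{>}).
#' @param denominator \code{"bound"} (fraction of bound structures,
#'   default) or \code{"ungapped"} (fraction of structures ungapped at
#'   the position).
#' @return Sorted integer vector of positions.
#' @export
paratope_positions <- function(profile, threshold = 0.10,
                               denominator = c("bound", "ungapped")) {
  denominator <- match.arg(denominator)
  prop <- if (denominator == "bound") profile$propensity else
    profile$propensity_ungapped
  sort(profile$position[!is.na(prop) & prop > threshold])
}
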