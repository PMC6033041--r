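#' Loop lengths on the full (unreduced) alignment
#'
#' Loop lengths are counted on the full-length alignment so that
#' low-occupancy central loop columns are included.
#'
#' @param full_aln An unreduced \code{numbered_alignment}.
#' @param columns Full-scheme column positions of the loop span.
#' @param loop_name Loop label for the records.
#' @return List with \code{records} (data frame: \code{id},
#'   \code{loop}, \code{seq} (ungapped), \code{length},
#'   \code{all_gap}) and \code{summary} (mean, sd, median).
#' @export
loop_lengths <- function(full_aln, columns, loop_name = "loop") {
  mat <- full_aln$mat[, columns, drop = FALSE]
  lens <- apply(mat, 1, function(r) sum(r != GAP))
  seqs <- apply(mat, 1, function(r) paste(r[r != GAP], collapse = ""))
  records <- data.frame(id = full_aln$ids, loop = loop_name,
                        seq = seqs, length = as.integer(lens),
                        all_gap = lens == 0L,
                        stringsAsFactors = FALSE)
  if (any(records$all_gap)) {
    message("loop_lengths: ", sum(records$all_gap),
            " sequence(s) have an all-gap ", loop_name, " span")
  }
  list(records = records,
       summary = list(mean = mean(lens), sd = stats::sd(lens),
                      median = stats::median(lens)))
}

#' Normalized loop-length histogram
#'
#' @param lengths Integer vector of loop lengths, or the \code{records}
#'   data frame from [loop_lengths()].
#' @return Named probability vector over the observed integer lengths
#'   (sums to 1).
#' @export
length_distribution <- function(lengths) {
  if (is.data.frame(lengths)) lengths <- lengths$length
  if (length(lengths) == 0L) stop("no lengths given")
  tab <- table(lengths)
  p <- as.numeric(tab) / sum(tab)
  names(p) <- names(tab)
  p
}

#' Comparison configuration
#'
#' Defaults are the standard analysis values: gap-column threshold
#' 0.85, contact cutoff 5 Angstrom, paratope propensity threshold
#' 0.10, conservation subsampling with 6 draws of 90 sequences and a
#' 2-sigma flag.
#'
#' @param gap_threshold Gap fraction above which alignment columns are
#'   dropped.
#' @param contact_cutoff Antigen contact cutoff, Angstrom.
#' @param propensity_threshold Paratope propensity threshold.
#' @param n_draws,draw_size,sigma_mult Conservation-significance
#'   subsampling parameters.
#' @param kl_base Log base for KL divergences ("e" or "2").
#' @param kl_pseudocount Smoothing pseudocount for KL divergences.
#' @param unique_loops Deduplicate identical loop sequences before
#'   per-loop Hamming summaries (default \code{TRUE}).
#' @param loop_fit \code{"self"}: loop RMSD fitted on the loop's own
#'   common positions (default); \code{"framework"} also reported.
#' @param seed Integer seed for the stochastic steps.
#' @return A \code{comparison_config} list.
#' @export
comparison_config <- function(gap_threshold = 0.85,
                              contact_cutoff = 5.0,
                              propensity_threshold = 0.10,
                              n_draws = 6, draw_size = 90,
                              sigma_mult = 2,
                              kl_base = "e", kl_pseudocount = 1e-3,
                              unique_loops = TRUE,
                              loop_fit = c("self", "framework"),
                              seed = 1L) {
  structure(list(gap_threshold = gap_threshold,
                 contact_cutoff = contact_cutoff,
                 propensity_threshold = propensity_threshold,
                 n_draws = n_draws, draw_size = draw_size,
                 sigma_mult = sigma_mult,
                 kl_base = kl_base, kl_pseudocount = kl_pseudocount,
                 unique_loops = unique_loops,
                 loop_fit = match.arg(loop_fit),
                 seed = as.integer(seed)),
            class = "comparison_config")
}

#' Assemble a dataset bundle for [run_comparison()]
#'
#' @param records List of \code{complex_record}s.
#' @param numbering List of \code{numbered_sequence}s, parallel to
#'   \code{records}.
#' @param name Dataset label.
#' @param region_labels Optional full-scheme region labels (FR1..FR4,
#'   H1..H3), e.g. a generated family's \code{region_labels}; if
#'   absent, the standard 126-position spans are assumed after
#'   reduction.
#' @return A \code{comparison_dataset} list.
#' @export
comparison_dataset <- function(records, numbering, name,
                               region_labels = NULL) {
  stopifnot(length(records) == length(numbering))
  structure(list(records = records, numbering = numbering, name = name,
                 region_labels = region_labels),
            class = "comparison_dataset")
}

#' Load a generated synthetic family as a comparison dataset
#'
#' @param family Result of [generate_family()] (or a family directory
#'   containing \code{manifest.tsv} and \code{ground_truth.json}).
#' @param dedup Passed to [load_dataset()].
#' @return A \code{comparison_dataset}.
#' @export
family_dataset <- function(family, dedup = FALSE) {
  if (is.character(family)) {
    gt <- jsonlite::read_json(file.path(family, "ground_truth.json"),
                              simplifyVector = TRUE)
    family <- list(dir = family,
                   manifest = file.path(family, "manifest.tsv"),
                   ground_truth = gt)
  }
  records <- load_dataset(family$manifest, dedup = dedup)
  numbering <- family_numbering(family)
  comparison_dataset(records, numbering,
                     name = family$ground_truth$name,
                     region_labels = family$ground_truth$region_labels)
}

# Per-dataset analysis shared by run_comparison().
analyse_dataset <- function(ds, config) {
  num <- ds$numbering
  full_aln <- load_numbering_tables(num)
  red_aln <- reduce_alignment(full_aln, config$gap_threshold)
  map <- if (!is.null(ds$region_labels)) {
    region_map_from_labels(ds$region_labels[red_aln$full_positions])
  } else {
    region_map(p = ncol(red_aln$mat))
  }
  scheme_length <- ncol(full_aln$mat)

  profile <- conservation_profile(red_aln)
  logo_bits <- logo_matrix(red_aln, mode = "bits")
  logo_freq <- logo_matrix(red_aln, mode = "frequency")

  coords <- coord_sets(ds$records, num, scheme_length)
  fr_full <- reduced_to_full(red_aln, region_positions(map, "FR"))
  fr_rmsd <- pairwise_rmsd(coords, fr_full)

  loops <- c("H1", "H2", "H3")
  loop_res <- lapply(loops, function(nm) {
    red_pos <- region_positions(map, nm)
    full_pos <- reduced_to_full(red_aln, red_pos)
    span <- full_region_span(red_aln, map, nm)
    ll <- loop_lengths(full_aln, span, nm)
    # per-loop Hamming on the full alignment loop columns, unique loop
    # sequences by default
    ham_mat <- full_aln$mat[, span, drop = FALSE]
    if (isTRUE(config$unique_loops)) {
      keys <- apply(ham_mat, 1, paste, collapse = "")
      ham_mat <- ham_mat[!duplicated(keys), , drop = FALSE]
    }
    ham <- if (nrow(ham_mat) >= 2L) pairwise_hamming(ham_mat) else NULL
    list(
      name = nm,
      lengths = ll,
      distribution = length_distribution(ll$records),
      n_unique = if (isTRUE(config$unique_loops)) nrow(ham_mat) else
        length(unique(apply(full_aln$mat[, span, drop = FALSE], 1,
                            paste, collapse = ""))),
      hamming = ham,
      rmsd_self_fit = pairwise_rmsd(coords, full_pos),
      rmsd_fr_fit = pairwise_rmsd(coords, fr_full, full_pos)
    )
  })
  names(loop_res) <- loops

  bound <- vapply(ds$records, function(r) r$state == "bound", logical(1))
  paratope <- NULL
  contacts <- NULL
  if (any(bound)) {
    prop <- contact_propensity(ds$records, num, scheme_length,
                               cutoff = config$contact_cutoff)
    pset_full <- paratope_positions(prop, config$propensity_threshold)
    contacts <- contact_count_stats(ds$records,
                                    cutoff = config$contact_cutoff)
    paratope <- list(profile = prop, positions_full = pset_full,
                     breadth = length(pset_full))
  }

  list(name = ds$name, n = length(ds$records),
       full_aln = full_aln, red_aln = red_aln, map = map,
       scheme_length = scheme_length,
       p_reduced = ncol(red_aln$mat),
       profile = profile, logo_bits = logo_bits, logo_freq = logo_freq,
       coords = coords, fr_rmsd = fr_rmsd, loops = loop_res,
       paratope = paratope, contacts = contacts,
       species = table(vapply(ds$records, `[[`, character(1), "species")))
}

#' Run the full two-dataset comparison
#'
#' Orchestrates every analysis stage for two datasets -- alignment
#' reduction, conservation profiles and logo matrices, per-loop
#' Hamming diversity, loop-length distributions with KL divergence,
#' framework and loop pairwise RMSD (both loop-self and framework
#' fits), contact propensity with paratope breadth, cross-dataset
#' conservation significance, and the unpaired t tests on the pairwise
#' distance distributions. Deterministic given \code{config$seed}.
#'
#' @param a,b \code{comparison_dataset} bundles (see
#'   [comparison_dataset()], [family_dataset()]).
#' @param config A [comparison_config()].
#' @return A \code{comparison_report} list; see [write_report()] for
#'   serialization.
#' @export
run_comparison <- function(a, b, config = comparison_config()) {
  stopifnot(inherits(a, "comparison_dataset"),
            inherits(b, "comparison_dataset"))
  if (length(a$records) < 2L || length(b$records) < 2L) {
    stop("each dataset needs at least 2 records for pairwise statistics")
  }
  da <- analyse_dataset(a, config)
  db <- analyse_dataset(b, config)

  # cross-dataset loop statistics
  loops <- c("H1", "H2", "H3")
  cross_loops <- lapply(loops, function(nm) {
    la <- da$loops[[nm]]
    lb <- db$loops[[nm]]
    kl_ab <- kl_divergence(la$distribution, lb$distribution,
                           base = config$kl_base,
                           pseudocount = config$kl_pseudocount)
    tt_ham <- if (!is.null(la$hamming) && !is.null(lb$hamming)) {
      t_test_unpaired(pairwise_values(la$hamming),
                      pairwise_values(lb$hamming))
    }
    tt_rmsd <- t_test_unpaired(pairwise_values(la$rmsd_fr_fit),
                               pairwise_values(lb$rmsd_fr_fit))
    tt_len <- t_test_unpaired(la$lengths$records$length,
                              lb$lengths$records$length)
    list(loop = nm, kl_length_a_from_b = kl_ab,
         t_hamming = tt_ham, t_rmsd_fr_fit = tt_rmsd,
         t_length = tt_len)
  })
  names(cross_loops) <- loops

  tt_fr <- t_test_unpaired(pairwise_values(da$fr_rmsd),
                           pairwise_values(db$fr_rmsd))

  # conservation significance of A against subsamples of B (and the
  # reverse), over the full-scheme columns retained in both
  # reductions; if the pool is no larger than draw_size the draws
  # switch to with-replacement resampling so that the spread is
  # defined
  common_full <- intersect(da$red_aln$full_positions,
                           db$red_aln$full_positions)
  sub_common <- function(d) {
    idx <- full_to_reduced(d$red_aln, common_full)
    new_alignment(ids = d$red_aln$ids, positions = common_full,
                  mat = d$red_aln$mat[, idx, drop = FALSE])
  }
  boot <- NULL
  if (length(common_full) > 0L) {
    ca_aln <- sub_common(da)
    cb_aln <- sub_common(db)
    mk_boot <- function(target_aln, pool_aln, seed_off) {
      draw_size <- min(config$draw_size, nrow(pool_aln$mat))
      replace <- draw_size >= nrow(pool_aln$mat)
      bootstrap_conservation_compare(
        conservation_profile(target_aln), pool_aln,
        n_draws = config$n_draws, draw_size = draw_size,
        sigma_mult = config$sigma_mult, replace = replace,
        seed = config$seed + seed_off)
    }
    ba <- mk_boot(ca_aln, cb_aln, 0L)
    bb <- mk_boot(cb_aln, ca_aln, 1L)
    fr_full <- reduced_to_full(da$red_aln, region_positions(da$map, "FR"))
    boot <- list(
      a_vs_b = ba, b_vs_a = bb,
      n_common_positions = length(common_full),
      n_flagged_a = sum(ba$flag),
      n_flagged_a_fr = sum(ba$flag[ba$position %in% fr_full]),
      n_flagged_b = sum(bb$flag))
  }

  structure(list(
    config = unclass(config),
    a = da, b = db,
    cross = list(loops = cross_loops, t_fr_rmsd = tt_fr,
                 bootstrap = boot)
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report:", x$a$name, "vs", x$b$name, "\n")
  cat(sprintf("  framework RMSD: %.2f +/- %.2f vs %.2f +/- %.2f A\n",
              x$a$fr_rmsd$summary$mean, x$a$fr_rmsd$summary$sd,
              x$b$fr_rmsd$summary$mean, x$b$fr_rmsd$summary$sd))
  for (nm in names(x$a$loops)) {
    cat(sprintf("  %s RMSD (self fit): %.2f vs %.2f A; KL(len) %.3f\n",
                nm, x$a$loops[[nm]]$rmsd_self_fit$summary$mean,
                x$b$loops[[nm]]$rmsd_self_fit$summary$mean,
                x$cross$loops[[nm]]$kl_length_a_from_b))
  }
  if (!is.null(x$a$paratope)) {
    cat(sprintf("  paratope breadth: %d vs %d positions\n",
                x$a$paratope$breadth, x$b$paratope$breadth))
  }
  invisible(x)
}

# Flatten the report to the serializable summary written as JSON.
report_summary <- function(report) {
  ds_sum <- function(d) {
    out <- list(
      name = d$name, n = d$n,
      scheme_length = d$scheme_length, p_reduced = d$p_reduced,
      n_framework_positions = length(region_positions(d$map, "FR")),
      n_loop_positions = length(region_positions(d$map, "loops")),
      framework_rmsd = d$fr_rmsd$summary,
      loops = lapply(d$loops, function(l) {
        list(length_mean = l$lengths$summary$mean,
             length_sd = l$lengths$summary$sd,
             length_median = l$lengths$summary$median,
             n_unique = l$n_unique,
             hamming = if (!is.null(l$hamming)) l$hamming$summary,
             rmsd_self_fit = l$rmsd_self_fit$summary,
             rmsd_fr_fit = l$rmsd_fr_fit$summary)
      }),
      species = as.list(d$species))
    if (!is.null(d$paratope)) {
      out$paratope_breadth <- d$paratope$breadth
      out$paratope_positions <- d$paratope$positions_full
      out$mean_contacts_per_structure <- d$contacts$mean
      out$sd_contacts_per_structure <- d$contacts$sd
    }
    out
  }
  list(
    config = report$config,
    a = ds_sum(report$a),
    b = ds_sum(report$b),
    cross = list(
      t_fr_rmsd = report$cross$t_fr_rmsd,
      loops = lapply(report$cross$loops, function(cl) {
        list(kl_length_a_from_b = cl$kl_length_a_from_b,
             t_hamming = cl$t_hamming,
             t_rmsd_fr_fit = cl$t_rmsd_fr_fit,
             t_length = cl$t_length)
      }),
      bootstrap = if (!is.null(report$cross$bootstrap)) {
        list(n_common_positions =
               report$cross$bootstrap$n_common_positions,
             n_flagged_a = report$cross$bootstrap$n_flagged_a,
             n_flagged_a_fr = report$cross$bootstrap$n_flagged_a_fr,
             n_flagged_b = report$cross$bootstrap$n_flagged_b)
      }
    )
  )
}

#' Write a comparison report to disk
#'
#' Writes \code{report.json} (summary numbers), per-dataset TSVs
#' (conservation profile, logo matrix, pairwise matrices, loop
#' records, contact propensity) and the conservation-significance
#' flags. Rerunning with the same config seed reproduces
#' \code{report.json} byte-identically.
#'
#' @param report A \code{comparison_report}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_summary(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  for (side in c("a", "b")) {
    d <- report[[side]]
    tag <- paste0(side, "_", d$name)
    wt(d$profile, paste0(tag, "_conservation.tsv"))
    write_logo_tsv(d$logo_bits, file.path(dir, paste0(tag, "_logo.tsv")))
    wt(as.data.frame(d$fr_rmsd$values),
       paste0(tag, "_framework_rmsd.tsv"))
    for (nm in names(d$loops)) {
      wt(d$loops[[nm]]$lengths$records,
         paste0(tag, "_", nm, "_loops.tsv"))
    }
    if (!is.null(d$paratope)) {
      wt(d$paratope$profile, paste0(tag, "_propensity.tsv"))
    }
  }
  if (!is.null(report$cross$bootstrap)) {
    wt(report$cross$bootstrap$a_vs_b, "conservation_flags_a_vs_b.tsv")
    wt(report$cross$bootstrap$b_vs_a, "conservation_flags_b_vs_a.tsv")
  }
  invisible(dir)
}
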