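#' Filter assemblies by BUSCO completeness
#'
#' Retains records whose BUSCO score is at least `busco_min` (boundary
#' inclusive); records missing a score are discarded with a reason.
#'
#' @param trait_table data.frame with at least `species` and `busco_score`.
#' @param busco_min minimum score in \[0,1\] (default 0.90).
#' @return list with `retained` and `discarded` data.frames (the latter
#'   with a `reason` column); counts reported via `message()`.
#' @export
filter_assemblies <- function(trait_table, busco_min = 0.90) {
  stopifnot(busco_min >= 0, busco_min <= 1)
  tt <- validate_trait_table(trait_table)
  if (!"busco_score" %in% names(tt))
    stop("trait table has no busco_score column")
  missing <- is.na(tt$busco_score)
  low <- !missing & tt$busco_score < busco_min
  keep <- !missing & !low
  discarded <- tt[!keep, , drop = FALSE]
  discarded$reason <- ifelse(missing[!keep], "missing busco_score",
                             sprintf("busco_score < %g", busco_min))
  message(sprintf("BUSCO filter (>= %g): retained %d, discarded %d (%d missing score)",
                  busco_min, sum(keep), sum(!keep), sum(missing)))
  list(retained = tt[keep, , drop = FALSE], discarded = discarded)
}

#' Study configuration for [run_study()]
#'
#' @param trees a `multiPhylo`/list of trees, or a Newick file path.
#' @param trait_table a trait data.frame, or a TSV path (see
#'   [read_trait_table()]).
#' @param fasta_dir optional directory of per-species FASTA files named
#'   `<species>.fa`/`.fasta` (optionally gzipped); when given, per-genome
#'   microsatellite profiles are computed and override the trait table's
#'   content columns.
#' @param output_dir optional directory for TSV/JSON outputs.
#' @param busco_min BUSCO retention threshold (default 0.90).
#' @param min_group_n minimum species per group for per-order rates
#'   (default 10).
#' @param n_sim phylogenetic-ANOVA null simulations per test (default 100).
#' @param n_maps stochastic maps for the censored rate test (default 100).
#' @param n_boot bootstrap replicates per phylogenetic linear model
#'   (default 100).
#' @param n_anova_trees number of trees on which each phylogenetic ANOVA is
#'   repeated (default: all trees).
#' @param alpha significance level (default 0.05).
#' @param seed master RNG seed; all stage streams derive from it.
#' @return list of class `study_config`.
#' @export
study_config <- function(trees, trait_table, fasta_dir = NULL,
                         output_dir = NULL, busco_min = 0.90,
                         min_group_n = 10, n_sim = 100, n_maps = 100,
                         n_boot = 100, n_anova_trees = NULL, alpha = 0.05,
                         seed = 1L) {
  stopifnot(busco_min >= 0, busco_min <= 1, n_sim >= 1, n_maps >= 1,
            n_boot >= 1, alpha > 0, alpha < 1)
  cfg <- as.list(environment())
  class(cfg) <- "study_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the comparative study end-to-end
#'
#' Orchestrates the full analysis: (1) optional genome scans for
#' microsatellite profiles; (2) BUSCO filtering and joining of traits to
#' the tree set; (3) global and per-order Brownian rates on content per
#' Mbp; (4) tip rates on total microsatellite bp; (5) phylogenetic ANOVA of
#' content by centromere type (each content response, repeated over trees);
#' (6) Mk fit, stochastic maps, and the censored two-rate tally; (7)
#' phylogenetic linear models of content and tip rate on chromosome number
#' and genome size across all trees.  Species missing a field are excluded
#' only from the analyses needing that field.  Every random stage draws its
#' seed from the master seed, so reruns are reproducible.
#'
#' @param config a [study_config()].
#' @return list of class `study_report` with per-stage results and the
#'   echoed configuration; written as JSON/TSV when `output_dir` is set.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  stage_seeds <- stats::setNames(
    sample.int(.Machine$integer.max, 6),
    c("scan", "anova", "mk", "maps", "censored", "lm"))

  trees <- stage("load trees", {
    tr <- config$trees
    if (is.character(tr)) tr <- read_newick(tr)
    if (inherits(tr, "phylo")) tr <- structure(list(tr), class = "multiPhylo")
    lapply(tr, validate_tree)
    tr
  })
  tt <- stage("load traits", {
    x <- config$trait_table
    if (is.character(x)) read_trait_table(x) else validate_trait_table(x)
  })

  profiles <- NULL
  if (!is.null(config$fasta_dir)) {
    profiles <- stage("scan genomes", {
      set.seed(stage_seeds["scan"])
      files <- list.files(config$fasta_dir,
                          pattern = "\\.(fa|fasta|fna)(\\.gz)?$",
                          full.names = TRUE)
      if (!length(files)) stop("no FASTA files found")
      pr <- lapply(files, function(f) scan_fasta(f)$profile)
      rows <- do.call(rbind, lapply(pr, profile_row))
      rows$species <- normalize_labels(rows$species)
      rows
    })
    tt <- stage("merge profiles", {
      tt$content_per_mbp <- NULL; tt$total_bp <- NULL
      merge(tt, profiles[, c("species", "total_bp", "content_per_mbp")],
            by = "species")
    })
  }

  filt <- stage("busco filter", filter_assemblies(tt, config$busco_min))
  tt <- filt$retained

  tree_tips <- normalize_labels(trees[[1]]$tip.label)
  analysed <- intersect(tt$species, tree_tips)
  if (!length(analysed)) stop("stage 'join': no species shared by traits and trees")
  extra <- setdiff(tree_tips, tt$species)
  if (length(extra))
    message(sprintf("pruning %d tree tips without retained traits", length(extra)))
  trees <- stage("join", {
    out <- lapply(trees, function(tr)
      prune_to(tr, tr$tip.label[tree_tips %in% analysed]))
    class(out) <- "multiPhylo"
    out
  })
  tt <- tt[tt$species %in% analysed, , drop = FALSE]
  tree1 <- trees[[1]]

  content <- stats::setNames(tt$content_per_mbp, tt$species)
  totbp <- stats::setNames(tt$total_bp, tt$species)

  global_fit <- stage("global BM rate",
                      fit_bm(tree1, content, units = "bp/Mbp"))
  order_fits <- NULL
  if ("order_label" %in% names(tt)) {
    ord <- stats::setNames(tt$order_label, tt$species)
    ok <- !is.na(ord)
    order_fits <- stage("per-order rates", {
      if (sum(ok) >= 2)
        suppressMessages(rates_by_group(
          prune_to(tree1, names(ord)[ok]), content[ok], ord[ok],
          min_n = config$min_group_n, units = "bp/Mbp"))
      else NULL
    })
  }
  tips <- stage("tip rates", tip_rates(tree1, totbp))

  anova_results <- NULL
  ct <- if ("centromere_type" %in% names(tt))
    stats::setNames(tt$centromere_type, tt$species) else NULL
  has_ct <- !is.null(ct) && length(unique(stats::na.omit(ct))) == 2 &&
    all(table(stats::na.omit(ct)) >= 2)
  if (has_ct) {
    anova_results <- stage("phylo ANOVA by centromere type", {
      set.seed(stage_seeds["anova"])
      responses <- c(grep("^bp_[2-6]mer$", names(tt), value = TRUE),
                     "total_bp", "content_per_mbp")
      responses <- intersect(responses, names(tt))
      nt_use <- min(length(trees),
                    config$n_anova_trees %||% length(trees))
      res <- list()
      for (resp in responses) {
        yv <- stats::setNames(tt[[resp]], tt$species)
        okr <- !is.na(yv) & !is.na(ct)
        per_tree <- lapply(trees[seq_len(nt_use)], function(tr) {
          sub <- prune_to(tr, tr$tip.label[
            normalize_labels(tr$tip.label) %in% names(yv)[okr]])
          phylo_anova(sub, yv[okr], ct[okr], n_sim = config$n_sim)
        })
        res[[resp]] <- data.frame(
          tree = seq_len(nt_use),
          f_obs = vapply(per_tree, `[[`, numeric(1), "f_obs"),
          p_phylo = vapply(per_tree, `[[`, numeric(1), "p_phylo"),
          p_standard = vapply(per_tree, `[[`, numeric(1), "p_standard"))
      }
      res
    })
  }

  censored <- NULL
  if (has_ct) {
    censored <- stage("censored rate test", {
      okc <- !is.na(ct)
      sub1 <- prune_to(tree1, names(ct)[okc])
      set.seed(stage_seeds["mk"])
      mkfit <- fit_mk_ard(sub1, ct[okc])
      set.seed(stage_seeds["maps"])
      ## spread maps across the tree set, one map per (recycled) tree
      maps <- lapply(seq_len(config$n_maps), function(i) {
        tr <- trees[[((i - 1) %% length(trees)) + 1]]
        sub <- prune_to(tr, names(ct)[okc])
        sample_stochastic_map(sub, ct[okc], mkfit)
      })
      set.seed(stage_seeds["censored"])
      summ <- censored_over_maps(maps, content[okc], alpha = config$alpha)
      list(mk_fit = mkfit, summary = summ)
    })
  }

  lms <- stage("phylogenetic linear models", {
    set.seed(stage_seeds["lm"])
    rate <- stats::setNames(tips$rate, tips$species)
    out <- list()
    specs <- list(
      content_vs_chromosomes = list(y = content, xcol = "chromosome_number"),
      tip_rate_vs_chromosomes = list(y = rate, xcol = "chromosome_number"),
      content_vs_genome_size = list(y = content, xcol = "genome_size_mbp"),
      tip_rate_vs_genome_size = list(y = rate, xcol = "genome_size_mbp"))
    for (nm in names(specs)) {
      sp <- specs[[nm]]
      if (!sp$xcol %in% names(tt)) next
      X <- matrix(tt[[sp$xcol]], ncol = 1,
                  dimnames = list(tt$species, sp$xcol))
      out[[nm]] <- suppressMessages(
        lm_over_trees(trees, sp$y, X, n_boot = config$n_boot,
                      alpha = config$alpha))
    }
    out
  })

  report <- structure(list(
    config = config[setdiff(names(config), c("trees", "trait_table"))],
    seeds = c(master = config$seed, stage_seeds),
    n_species = nrow(tt), species = tt$species,
    filter = list(retained = nrow(tt), discarded = nrow(filt$discarded)),
    profiles = profiles,
    global_fit = global_fit, order_fits = order_fits,
    tip_rates = tips, anova = anova_results, censored = censored,
    lm = lms), class = "study_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Comparative study report: %d species, %d discarded by filters\n",
              x$n_species, x$filter$discarded))
  cat(sprintf("  global sigma^2 (content/Mbp): %.6g\n", x$global_fit$sigma2))
  if (!is.null(x$order_fits))
    cat(sprintf("  per-order rates: %d groups fit\n", length(x$order_fits)))
  if (!is.null(x$censored))
    cat(sprintf("  censored test: %d/%d maps favored two rates\n",
                x$censored$summary$n_two_rate, x$censored$summary$n_maps))
  for (nm in names(x$lm)) {
    t <- x$lm[[nm]]$tally
    cat(sprintf("  %s: %d/%d trees significant (%d positive slopes)\n",
                nm, t$n_significant, t$n_trees, t$n_positive))
  }
  invisible(x)
}

## serialise the report: JSON for scalar results, TSV for tables
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$tip_rates, file.path(dir, "tip_rates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$profiles))
    utils::write.table(report$profiles, file.path(dir, "profiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  js <- list(
    seeds = as.list(report$seeds),
    n_species = report$n_species,
    global_sigma2 = report$global_fit$sigma2,
    global_root_state = report$global_fit$root_state,
    order_sigma2 = if (!is.null(report$order_fits))
      lapply(report$order_fits, `[[`, "sigma2"),
    censored = if (!is.null(report$censored)) list(
      n_two_rate = report$censored$summary$n_two_rate,
      n_maps = report$censored$summary$n_maps,
      median_rates = as.list(apply(
        report$censored$summary$rates[, 2:3], 2, stats::median))),
    lm_tallies = lapply(report$lm, function(f) as.list(f$tally[1, ])))
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
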