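#' Simulate a birth-death tree conditioned on the number of extant taxa
#'
#' Ultrametric tree of extant species under a constant-rate birth-death
#' process (time units: My).  Uses the global RNG stream; seed with
#' [set.seed()].
#'
#' @param n_taxa number of extant tips (>= 3).
#' @param birth,death per-lineage speciation and extinction rates per My;
#'   `birth > death >= 0`.
#' @return an ultrametric `phylo`.
#' @export
simulate_bd_tree <- function(n_taxa, birth, death = 0) {
  if (n_taxa < 3L) stop("n_taxa must be >= 3")
  if (!(birth > death) || death < 0)
    stop("require birth > death >= 0")
  tr <- ape::rphylo(n_taxa, birth, death)
  validate_tree(tr)
  tr
}

#' Simulate Brownian motion on a tree
#'
#' Adds independent Normal(0, `sigma2 * length`) increments along every
#' branch, returning the full node-wise history.  Multiple replicates share
#' the tree traversal, so large simulation nulls are cheap.
#'
#' @param tree a `phylo`.
#' @param sigma2 Brownian rate, (trait units)^2 per My; `>= 0`.
#' @param root_value trait value at the root.
#' @param nsim number of independent replicates.
#' @return list with `tips` (matrix, tips x nsim, rownames = tip labels)
#'   and `nodes` (matrix over all nodes, tips first).
#' @export
simulate_bm <- function(tree, sigma2, root_value = 0, nsim = 1) {
  validate_tree(tree)
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  simulate_bm_edges(tree, sigma2 * tree$edge.length, root_value, nsim)
}

## shared machinery: per-edge variances -> node-wise BM realisations
simulate_bm_edges <- function(tree, edge_var, root_value, nsim) {
  nt <- ape::Ntip(tree)
  nn <- tree$Nnode
  ptree <- ape::reorder.phylo(tree, "postorder")
  ## preserve the caller's edge order when variances were supplied per edge
  key <- paste(tree$edge[, 1], tree$edge[, 2], sep = ",")
  pkey <- paste(ptree$edge[, 1], ptree$edge[, 2], sep = ",")
  ev <- edge_var[match(pkey, key)]
  e <- ptree$edge
  vals <- matrix(0, nt + nn, nsim)
  root <- nt + 1L
  vals[root, ] <- root_value
  for (i in rev(seq_len(nrow(e)))) {
    vals[e[i, 2], ] <- vals[e[i, 1], ] +
      stats::rnorm(nsim, 0, sqrt(ev[i]))
  }
  tips <- vals[seq_len(nt), , drop = FALSE]
  rownames(tips) <- tree$tip.label
  list(tips = tips, nodes = vals)
}

#' Simulate state-dependent (two-rate) Brownian motion on a stochastic map
#'
#' Along every branch the accumulated variance is the segment-weighted sum
#' `sum(sigma2[state] * duration)`, so a branch painted entirely in one
#' state behaves exactly like single-rate Brownian motion at that state's
#' rate.
#'
#' @param map a `simmap` (e.g. from [simulate_mk()] or
#'   [sample_stochastic_map()]).
#' @param sigma2_by_state named numeric of per-state rates (names matching
#'   the map's states).
#' @inheritParams simulate_bm
#' @return as [simulate_bm()].
#' @export
simulate_bm_two_rate <- function(map, sigma2_by_state, root_value = 0,
                                 nsim = 1) {
  if (is.null(map$mapped.edge)) stop("map must carry a mapped.edge matrix")
  states <- colnames(map$mapped.edge)
  if (!all(states %in% names(sigma2_by_state)))
    stop("sigma2_by_state must name every map state")
  if (any(sigma2_by_state < 0)) stop("rates must be >= 0")
  ev <- as.vector(map$mapped.edge %*% sigma2_by_state[states])
  tree <- map
  class(tree) <- "phylo"
  simulate_bm_edges(tree, ev, root_value, nsim)
}

#' Simulate a two-state Markov character with its full history
#'
#' Exact (Gillespie) simulation of the two-state continuous-time Markov
#' chain along every branch; the realised history is returned as a
#' `simmap` whose tip states are the simulated character.
#'
#' @param tree a `phylo`.
#' @param q01 rate from the first to the second state (per My).
#' @param q10 reverse rate.
#' @param root_state index (1 or 2) or name of the root state.
#' @param states the two state names.
#' @return a `simmap` with `$states` (tip states) and `$node_state`.
#' @export
simulate_mk <- function(tree, q01, q10, root_state = 1,
                        states = c("holocentric", "monocentric")) {
  validate_tree(tree)
  if (q01 < 0 || q10 < 0) stop("rates must be >= 0")
  if (is.character(root_state)) root_state <- match(root_state, states)
  stopifnot(root_state %in% 1:2)
  nt <- ape::Ntip(tree)
  ptree <- ape::reorder.phylo(tree, "postorder")
  e <- ptree$edge; el <- ptree$edge.length
  ns <- integer(nt + tree$Nnode)
  ns[nt + 1L] <- root_state
  rates <- c(q01, q10)
  maps <- vector("list", nrow(e))
  for (i in rev(seq_len(nrow(e)))) {
    s <- ns[e[i, 1]]
    remain <- el[i]
    segs <- numeric(0); labs <- integer(0)
    repeat {
      r <- rates[s]
      w <- if (r > 0) stats::rexp(1, r) else Inf
      if (w >= remain) {
        segs <- c(segs, remain); labs <- c(labs, s)
        break
      }
      segs <- c(segs, w); labs <- c(labs, s)
      remain <- remain - w
      s <- 3L - s
    }
    maps[[i]] <- stats::setNames(segs, states[labs])
    ns[e[i, 2]] <- s
  }
  build_simmap(ptree, maps, states, ns)
}

#' Synthesise a genome with planted microsatellites
#'
#' Builds an i.i.d. background sequence with the requested GC content and
#' inserts perfect tandem repeats at known positions.  The ground-truth
#' locus table is produced by running the reference scanner
#' ([scan_sequence_ref()]) on the *finished* sequence, so repeats that
#' arise spontaneously in the background, or that abut a plant, are
#' captured exactly rather than approximated from the plant list.
#'
#' @param length genome length in bp.
#' @param plants data.frame with columns `motif` and `copies`, and
#'   optionally `start` (0-based; randomly placed without overlap when
#'   absent).  `NULL` for no plants.
#' @param gc background GC content in (0,1).
#' @param params [scan_params()] used for the truth scan.
#' @param sequence_id record id used in the truth table.
#' @return list with `seq` (character), `truth` (reference-scan locus
#'   table), `plants` (plant table with realised `start`/`end`),
#'   `sequence_id`.
#' @export
synth_genome <- function(length, plants = NULL, gc = 0.5,
                         params = scan_params(), sequence_id = "synth") {
  stopifnot(length >= 1, gc > 0, gc < 1)
  base <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  if (!is.null(plants) && nrow(plants) > 0) {
    plants$motif <- toupper(plants$motif)
    if (any(grepl("[^ACGT]", plants$motif)))
      stop("plant motifs must be A/C/G/T")
    plen <- nchar(plants$motif) * plants$copies
    if (is.null(plants$start)) {
      plants$start <- place_plants(length, plen)
    } else {
      o <- order(plants$start)
      s <- plants$start[o]; l <- plen[o]
      if (any(s < 0) || any(s + l > length))
        stop("plants fall outside the sequence")
      if (any(s[-1] < (s + l)[-length(s)]))
        stop("plants overlap")
    }
    for (i in seq_len(nrow(plants))) {
      run <- strsplit(strrep(plants$motif[i], plants$copies[i]), "")[[1]]
      base[(plants$start[i] + 1L):(plants$start[i] + plen[i])] <- run
    }
    plants$end <- plants$start + plen
  }
  seq <- paste(base, collapse = "")
  list(seq = seq,
       truth = scan_sequence_ref(sequence_id, seq, params),
       plants = plants, sequence_id = sequence_id)
}

## non-overlapping random placement by rejection
place_plants <- function(length, plant_lengths) {
  starts <- integer(length(plant_lengths))
  placed <- matrix(numeric(0), ncol = 2)
  for (i in order(plant_lengths, decreasing = TRUE)) {
    L <- plant_lengths[i]
    if (L > length) stop("plant longer than the sequence")
    ok <- FALSE
    for (try in seq_len(1000L)) {
      s <- sample.int(length - L + 1L, 1L) - 1L
      if (nrow(placed) == 0 ||
          all(s + L <= placed[, 1] | s >= placed[, 2])) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place plants without overlap")
    placed <- rbind(placed, c(s, s + L))
    starts[i] <- s
  }
  starts
}

#' Write sequences to a FASTA file
#' @param seqs named character vector of sequences.
#' @param path output path (plain text).
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Configuration for a synthetic comparative study
#'
#' Defaults emulate the shape of a broad insect-genome comparative study: a
#' 200-species time-calibrated tree a few hundred My deep, a 100-tree
#' pseudo-posterior (branch-length jitter around the true tree),
#' centromere type evolving under a two-state Markov process, microsatellite
#' content (bp/Mbp) evolving under state-dependent Brownian motion with a
#' higher monocentric rate, genome size evolving as Brownian motion on the
#' log scale with a positive effect on content, chromosome number with no
#' effect, and a minority of assemblies given sub-0.90 BUSCO scores to
#' exercise the quality filter.
#'
#' @param n_taxa number of species.
#' @param birth,death birth-death rates per My.
#' @param n_trees size of the pseudo-posterior tree set.
#' @param tree_jitter_sd lognormal sd of per-branch length jitter for the
#'   pseudo-posterior.
#' @param sigma2_by_state named per-state Brownian rates for content
#'   ((bp/Mbp)^2/My); equal values give a single-rate study.
#' @param root_content root microsatellite content (bp/Mbp).
#' @param q01,q10 centromere-type transition rates (first state ->
#'   second, and reverse, per My).
#' @param root_state root centromere state.
#' @param slope_genome_size effect of genome size (Mbp) on content
#'   (bp/Mbp per Mbp); 0 for a null study.
#' @param genome_size_root root genome size (Mbp).
#' @param genome_size_sigma2 Brownian rate of log genome size.
#' @param busco_low_frac fraction of species given BUSCO scores below 0.90.
#' @param genome_length length of each synthetic assembly (bp); 0 skips
#'   genome synthesis.
#' @param gc background GC content of synthetic assemblies.
#' @param seed integer seed; every simulate_study() stream derives from it.
#' @return list of class `study_sim_config`.
#' @export
study_sim_config <- function(n_taxa = 200, birth = 0.015, death = 0.005,
                             n_trees = 100, tree_jitter_sd = 0.1,
                             sigma2_by_state = c(holocentric = 1e4,
                                                 monocentric = 1e5),
                             root_content = 5000,
                             q01 = 0.005, q10 = 0.005,
                             root_state = "monocentric",
                             slope_genome_size = 10,
                             genome_size_root = 500,
                             genome_size_sigma2 = 5e-4,
                             busco_low_frac = 0.1,
                             genome_length = 20000, gc = 0.35,
                             seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_taxa >= 3, cfg$birth > cfg$death, cfg$death >= 0,
            cfg$q01 >= 0, cfg$q10 >= 0, all(cfg$sigma2_by_state >= 0),
            cfg$gc > 0, cfg$gc < 1,
            cfg$busco_low_frac >= 0, cfg$busco_low_frac < 1)
  class(cfg) <- "study_sim_config"
  cfg
}

## group tips into pseudo-orders: lineages crossing a fixed age horizon
assign_orders <- function(tree, frac = 0.6) {
  nt <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  age <- max(depth[seq_len(nt)]) - depth      # node ages before present
  horizon <- frac * max(age)
  e <- tree$edge
  crossing <- which(age[e[, 1]] > horizon & age[e[, 2]] <= horizon)
  lab <- stats::setNames(rep(NA_character_, nt), tree$tip.label)
  for (i in seq_along(crossing)) {
    sub <- e[crossing[i], 2]
    tips <- if (sub <= nt) sub else
      ape::prop.part(tree)[[sub - nt]]
    lab[tips] <- sprintf("order_%02d", i)
  }
  lab
}

#' Simulate a complete comparative study with known ground truth
#'
#' Generates every input the analysis pipeline consumes: a true
#' time-calibrated tree plus a jittered pseudo-posterior, a centromere-type
#' history, state-dependent microsatellite content with a configurable
#' genome-size effect, chromosome numbers (no effect), BUSCO scores with a
#' sub-threshold minority, and (optionally) per-species genome assemblies
#' with planted repeats whose truth tables come from the reference scanner.
#'
#' @param config a [study_sim_config()].
#' @return list with `trees` (multiPhylo pseudo-posterior; `trees[[1]]` is
#'   the true tree), `trait_table`, `genomes` (named list of
#'   [synth_genome()] results, or NULL), and `truth` (all generating
#'   parameters, the true history and per-species latent values).
#' @export
simulate_study <- function(config = study_sim_config()) {
  stopifnot(inherits(config, "study_sim_config"))
  set.seed(config$seed)
  states <- names(config$sigma2_by_state)
  tree <- simulate_bd_tree(config$n_taxa, config$birth, config$death)
  tree$tip.label <- sprintf("sp%03d", seq_len(config$n_taxa))
  history <- simulate_mk(tree, config$q01, config$q10,
                         root_state = config$root_state, states = states)
  ## genome size: BM on the log scale
  lgs <- simulate_bm(tree, config$genome_size_sigma2,
                     root_value = log(config$genome_size_root))$tips[, 1]
  genome_size <- exp(lgs)
  ## content: genome-size effect + state-dependent Brownian noise
  noise <- simulate_bm_two_rate(history, config$sigma2_by_state,
                                root_value = 0)$tips[, 1]
  content <- config$root_content +
    config$slope_genome_size * (genome_size - config$genome_size_root) +
    noise[tree$tip.label]
  content <- pmax(content, 10)
  chromosome_number <- 2 * pmax(2L, stats::rpois(config$n_taxa, 12))
  n_low <- round(config$busco_low_frac * config$n_taxa)
  busco <- stats::runif(config$n_taxa, 0.92, 0.999)
  low_idx <- if (n_low > 0) sample.int(config$n_taxa, n_low) else integer(0)
  busco[low_idx] <- stats::runif(n_low, 0.30, 0.85)
  ## centromere type observed at the tips, with occasional missing records
  ct <- unname(history$states[tree$tip.label])
  trait_table <- data.frame(
    species = tree$tip.label,
    content_per_mbp = unname(content),
    total_bp = unname(content * genome_size),
    centromere_type = ct,
    chromosome_number = chromosome_number,
    genome_size_mbp = unname(genome_size),
    busco_score = busco,
    order_label = unname(assign_orders(tree)),
    stringsAsFactors = FALSE)
  ## pseudo-posterior: per-branch lognormal jitter, re-ultrametrised by
  ## extending terminal branches to the common depth
  trees <- vector("list", config$n_trees)
  trees[[1]] <- tree
  if (config$n_trees > 1) {
    for (j in 2:config$n_trees) {
      tj <- tree
      sdl <- config$tree_jitter_sd
      tj$edge.length <- tj$edge.length *
        stats::rlnorm(length(tj$edge.length), -sdl^2 / 2, sdl)
      trees[[j]] <- extend_to_ultrametric(tj)
    }
  }
  class(trees) <- "multiPhylo"
  genomes <- NULL
  if (config$genome_length > 0) {
    genomes <- lapply(tree$tip.label, function(sp) {
      n_plants <- max(1L, stats::rpois(1, 5))
      periods <- sample(2:6, n_plants, replace = TRUE)
      plants <- data.frame(
        motif = vapply(periods, random_primitive_motif, character(1)),
        copies = sample(6:14, n_plants, replace = TRUE))
      synth_genome(config$genome_length, plants, gc = config$gc,
                   sequence_id = sp)
    })
    names(genomes) <- tree$tip.label
  }
  list(trees = trees, trait_table = trait_table, genomes = genomes,
       truth = list(config = config, tree = tree, history = history,
                    content_noise = noise, genome_size = genome_size,
                    busco_low = tree$tip.label[low_idx]))
}

## uniform-ish random motif that is primitive (no shorter period)
random_primitive_motif <- function(p) {
  repeat {
    m <- paste(sample(c("A", "C", "G", "T"), p, replace = TRUE),
               collapse = "")
    prim <- TRUE
    for (d in seq_len(p - 1)) {
      if (p %% d != 0) next
      if (identical(strrep(substr(m, 1, d), p / d), m)) { prim <- FALSE; break }
    }
    if (prim && length(unique(strsplit(m, "")[[1]])) > 1L) return(m)
  }
}

## make a tree ultrametric by extending terminal branches to equal depth
extend_to_ultrametric <- function(tree) {
  nt <- ape::Ntip(tree)
  d <- ape::node.depth.edgelength(tree)[seq_len(nt)]
  term <- match(seq_len(nt), tree$edge[, 2])
  tree$edge.length[term] <- tree$edge.length[term] + (max(d) - d)
  tree
}
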