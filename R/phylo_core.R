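#' Read Newick trees
#'
#' Reads one or more Newick trees from a file or from a literal Newick
#' string, validating that tip labels are unique and non-empty and that
#' branch lengths are non-negative.  Multi-tree files (e.g. a posterior
#' sample of time-calibrated trees) are supported.
#'
#' @param x a file path, or a character string containing Newick (detected
#'   by the presence of a terminal `;`).
#' @return an `ape::phylo` for a single tree, or a `multiPhylo` list for
#'   multi-tree input.
#' @export
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  is_text <- grepl(";", x, fixed = TRUE)
  tr <- if (is_text) ape::read.tree(text = x) else {
    if (!file.exists(x)) stop(sprintf("Newick file not found: %s", x))
    ape::read.tree(file = x)
  }
  if (is.null(tr)) stop("failed to parse Newick input")
  if (inherits(tr, "phylo")) validate_tree(tr) else {
    lapply(tr, validate_tree)
  }
  tr
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  labs <- tree$tip.label
  if (any(!nzchar(labs))) stop("empty tip labels")
  dup <- labs[duplicated(labs)]
  if (length(dup))
    stop(sprintf("duplicate tip labels: %s", paste(unique(dup), collapse = ", ")))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch lengths")
  invisible(tree)
}

#' Write Newick with full-precision branch lengths
#'
#' Branch lengths are emitted with 12 significant digits so that likelihood
#' computations are reproducible across round trips.
#'
#' @param tree a `phylo` or `multiPhylo`.
#' @param path output file; `""` returns the Newick string(s).
#' @export
write_newick <- function(tree, path = "") {
  ape::write.tree(tree, file = path, digits = 12)
}

#' Prune a tree to a set of taxa
#'
#' Induced subtree on the requested taxa: degree-2 internal nodes are
#' suppressed with their branch lengths summed, so root-to-tip path lengths
#' (and all patristic distances among retained tips) are preserved.
#'
#' @param tree a `phylo`.
#' @param taxa character vector of tip labels, at least 2, all present in
#'   the tree.
#' @return the induced `phylo`.
#' @export
prune_to <- function(tree, taxa) {
  validate_tree(tree)
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop(sprintf("taxa not in tree: %s", paste(missing, collapse = ", ")))
  if (length(taxa) < 2L) stop("need at least 2 taxa")
  ape::keep.tip(tree, taxa)
}

#' Test whether a tree is ultrametric
#'
#' @param tree a `phylo` with branch lengths.
#' @param rel_tol maximum allowed relative spread of root-to-tip path
#'   lengths.
#' @return logical.
#' @export
is_ultrametric <- function(tree, rel_tol = 1e-6) {
  validate_tree(tree)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  (max(d) - min(d)) <= rel_tol * max(d, .Machine$double.eps)
}

#' Normalise species labels
#'
#' Unifies whitespace and underscores (Newick convention friction) so trait
#' tables join cleanly to tip labels.
#'
#' @param x character vector of labels.
#' @return normalised labels (internal whitespace becomes a single
#'   underscore; leading/trailing whitespace dropped).
#' @export
normalize_labels <- function(x) {
  x <- trimws(x)
  gsub("\\s+", "_", x)
}

trait_numeric_cols <- c("content_per_mbp", "total_bp", "chromosome_number",
                        "genome_size_mbp", "busco_score")

#' Read a per-species trait table
#'
#' Tab-separated file with header; required column `species`, optional
#' columns `content_per_mbp`, `total_bp`, `centromere_type` (values
#' `holocentric`/`monocentric`, blank or NA for missing),
#' `chromosome_number` (diploid count), `genome_size_mbp`, `busco_score`
#' (in \[0,1\]), `order_label`.  Species labels are normalised with
#' [normalize_labels()].
#'
#' @param path TSV file.
#' @return data.frame keyed by `species`.
#' @export
read_trait_table <- function(path) {
  tt <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_trait_table(tt)
}

validate_trait_table <- function(tt) {
  if (!"species" %in% names(tt)) stop("trait table needs a 'species' column")
  tt$species <- normalize_labels(tt$species)
  if (anyDuplicated(tt$species))
    stop("duplicate species in trait table")
  for (cn in intersect(trait_numeric_cols, names(tt))) {
    tt[[cn]] <- as.numeric(tt[[cn]])
    if (any(tt[[cn]] < 0, na.rm = TRUE))
      stop(sprintf("negative values in column %s", cn))
  }
  if ("busco_score" %in% names(tt) &&
      any(tt$busco_score > 1, na.rm = TRUE))
    stop("busco_score must lie in [0,1]")
  if ("centromere_type" %in% names(tt)) {
    ct <- tt$centromere_type
    ct[!is.na(ct) & !nzchar(ct)] <- NA
    bad <- !is.na(ct) & !ct %in% c("holocentric", "monocentric")
    if (any(bad))
      stop(sprintf("invalid centromere_type: %s",
                   paste(unique(ct[bad]), collapse = ", ")))
    tt$centromere_type <- ct
  }
  tt
}

#' Write a trait table as TSV
#' @param tt trait table data.frame.
#' @param path output file.
#' @export
write_trait_table <- function(tt, path) {
  utils::write.table(tt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## match a named trait vector (or table) to the tree's tips, in tip order
match_to_tips <- function(tree, x, what = "trait") {
  labs <- normalize_labels(tree$tip.label)
  nm <- normalize_labels(names(x))
  if (is.null(nm)) stop(sprintf("%s must be named by species", what))
  missing <- setdiff(labs, nm)
  if (length(missing))
    stop(sprintf("%s missing for: %s", what, paste(missing, collapse = ", ")))
  out <- x[match(labs, nm)]
  names(out) <- tree$tip.label
  out
}

## resolve polytomies into arbitrary bifurcations with zero-length branches;
## contrast-based likelihoods are invariant to the arbitrary resolution
resolve_tree <- function(tree) {
  if (ape::is.binary.phylo(tree)) return(tree)
  ape::multi2di(tree, random = FALSE)
}
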