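# Feature-table processing and diversity computation. A feature table is a
# samples x taxa integer count matrix with unique dimnames; phylogenies are
# rooted `ape::phylo` trees whose tip labels cover the observed taxa.

validate_feature_table <- function(table) {
  if (!is.matrix(table)) table <- as.matrix(table)
  if (is.null(rownames(table)) || is.null(colnames(table))) {
    stop("feature table needs sample rownames and taxon colnames")
  }
  if (anyDuplicated(rownames(table)) || anyDuplicated(colnames(table))) {
    stop("sample and taxon IDs must be unique")
  }
  if (any(table < 0) || any(table != floor(table))) {
    stop("feature table must contain non-negative integer counts")
  }
  table
}

#' Read a samples-by-taxa feature table from TSV
#'
#' First column holds sample IDs; remaining columns are taxa. A BIOM-format
#' table can be read with [read_feature_table_biom()] instead.
#'
#' @param path TSV file path.
#' @return Integer matrix, samples x taxa.
#' @export
read_feature_table <- function(path) {
  dt <- data.table::fread(path)
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- as.character(dt[[1]])
  validate_feature_table(m)
}

#' Read a BIOM feature table
#'
#' Uses the biomformat package; BIOM stores taxa as rows, which are transposed
#' to the package's samples-x-taxa orientation.
#'
#' @param path BIOM file path.
#' @return Integer matrix, samples x taxa.
#' @export
read_feature_table_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    stop("reading BIOM requires the biomformat package")
  }
  b <- biomformat::read_biom(path)
  m <- t(as.matrix(biomformat::biom_data(b)))
  validate_feature_table(m)
}

#' Rarefy samples to a common depth
#'
#' Samples with fewer than `depth` total reads are dropped (reported via a
#' message); every retained sample is subsampled without replacement to
#' exactly `depth` reads. Seeded and reproducible.
#'
#' @param table Samples x taxa count matrix.
#' @param depth Target depth (default 15000 reads).
#' @param seed Integer RNG seed.
#' @return Rarefied count matrix.
#' @export
rarefy <- function(table, depth = 15000, seed = 1) {
  table <- validate_feature_table(table)
  assert_scalar_count(depth, "depth")
  totals <- rowSums(table)
  keep <- totals >= depth
  if (any(!keep)) {
    message(sprintf("rarefy: dropped %d/%d samples below depth %d",
                    sum(!keep), length(keep), depth))
  }
  table <- table[keep, , drop = FALSE]
  K <- ncol(table)
  with_rng(seed, {
    out <- t(apply(table, 1, function(x) {
      tabulate(sample(rep.int(seq_len(K), x), depth), nbins = K)
    }))
  })
  dimnames(out) <- dimnames(table)
  storage.mode(out) <- "integer"
  out
}

#' Prevalence filter
#'
#' Retains taxa present (count > 0) in at least `min_samples` samples. The
#' upstream convention is a threshold of about 25% of samples;
#' [prevalence_threshold()] expresses that default.
#'
#' @param table Samples x taxa count matrix.
#' @param min_samples Minimum number of samples a taxon must appear in.
#' @return Filtered count matrix.
#' @export
prevalence_filter <- function(table, min_samples) {
  table <- validate_feature_table(table)
  assert_scalar_count(min_samples, "min_samples")
  table[, colSums(table > 0) >= min_samples, drop = FALSE]
}

#' Default prevalence threshold: ~25% of samples
#'
#' @param n_samples Number of samples in the table.
#' @return Integer threshold.
#' @export
prevalence_threshold <- function(n_samples) {
  max(1L, as.integer(round(0.25 * n_samples)))
}

#' Centered log-ratio transform
#'
#' Per sample, `log(x + pseudocount)` centered by the sample mean of the logs,
#' so every transformed row sums to zero. Applied to raw (unrarefied) counts
#' by convention.
#'
#' @param table Samples x taxa count matrix.
#' @param pseudocount Positive constant added before the log (default 1).
#' @return Real matrix of CLR values.
#' @export
clr_transform <- function(table, pseudocount = 1) {
  table <- validate_feature_table(table)
  if (pseudocount <= 0) stop("pseudocount must be positive")
  lx <- log(table + pseudocount)
  lx - rowMeans(lx)
}

# Edge-by-tip incidence of a rooted tree: M[e, k] is TRUE when tip k descends
# through edge e. Shared by Faith's PD and unweighted UniFrac.
edge_tip_incidence <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo object")
  if (is.null(tree$edge.length)) stop("tree needs branch lengths")
  tr <- ape::reorder.phylo(tree, "postorder")
  K <- length(tr$tip.label)
  nnode <- tr$Nnode
  desc <- vector("list", K + nnode)
  for (i in seq_len(K)) desc[[i]] <- i
  E <- nrow(tr$edge)
  M <- matrix(FALSE, E, K)
  for (e in seq_len(E)) {
    child <- tr$edge[e, 2]
    M[e, desc[[child]]] <- TRUE
    parent <- tr$edge[e, 1]
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  list(incidence = M, lengths = tr$edge.length, tips = tr$tip.label)
}

#' Alpha diversity metrics
#'
#' Shannon entropy over non-zero proportions (log base 2 by default, the
#' QIIME 2 convention; switchable), Pielou's evenness `H / log(observed)`
#' (undefined for single-taxon samples), observed features, and — when a tree
#' is supplied — Faith's phylogenetic diversity, the summed branch length of
#' the union of root-to-tip paths of observed taxa.
#'
#' @param table Samples x taxa count matrix (typically rarefied).
#' @param tree Optional rooted `phylo` covering all observed taxa.
#' @param base Logarithm base for Shannon (default 2).
#' @return `data.table` with `sample_id`, `observed`, `shannon`, `pielou`,
#'   and `faith_pd` when a tree is given.
#' @export
alpha_metrics <- function(table, tree = NULL, base = 2) {
  table <- validate_feature_table(table)
  totals <- rowSums(table)
  if (any(totals == 0)) stop("sample(s) with zero total counts")
  p <- table / totals
  shannon <- -rowSums(ifelse(p > 0, p * log(p, base = base), 0))
  observed <- rowSums(table > 0)
  pielou <- ifelse(observed > 1, shannon / log(observed, base = base), NA_real_)
  out <- data.table::data.table(sample_id = rownames(table),
                                observed = as.integer(observed),
                                shannon = shannon, pielou = pielou)
  if (!is.null(tree)) {
    out[, "faith_pd" := faith_pd(table, tree)]
  }
  out[]
}

#' Faith's phylogenetic diversity
#'
#' @inheritParams alpha_metrics
#' @return Numeric vector, one value per sample.
#' @export
faith_pd <- function(table, tree) {
  table <- validate_feature_table(table)
  missing_tips <- setdiff(colnames(table), tree$tip.label)
  if (length(missing_tips)) {
    stop("taxa absent from tree: ", paste(head(missing_tips, 5), collapse = ", "))
  }
  inc <- edge_tip_incidence(tree)
  pres <- t(table[, inc$tips[inc$tips %in% colnames(table)], drop = FALSE] > 0)
  # restrict incidence to the table's taxa, aligned to `pres` row order
  M <- inc$incidence[, match(rownames(pres), inc$tips), drop = FALSE]
  hit <- (M %*% pres) > 0 # edges x samples
  as.numeric(crossprod(hit, inc$lengths))
}

#' Unweighted UniFrac distance matrix
#'
#' Presence/absence phylogenetic beta diversity: for each sample pair, the
#' branch length unique to one sample's observed taxa divided by the total
#' branch length observed in either, walked over the rooted tree.
#'
#' @param table Samples x taxa count matrix.
#' @param tree Rooted `phylo` covering the observed taxa.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
unweighted_unifrac <- function(table, tree) {
  table <- validate_feature_table(table)
  missing_tips <- setdiff(colnames(table), tree$tip.label)
  if (length(missing_tips)) {
    stop("taxa absent from tree: ", paste(head(missing_tips, 5), collapse = ", "))
  }
  if (any(rowSums(table > 0) == 0)) stop("sample(s) observing no taxa")
  inc <- edge_tip_incidence(tree)
  M <- inc$incidence[, match(colnames(table), inc$tips), drop = FALSE]
  P <- (M %*% t(table > 0)) > 0            # edges x samples presence
  Pl <- P * inc$lengths                    # length-weighted
  total <- colSums(Pl)
  shared <- crossprod(Pl, P)               # sum of lengths on edges in both
  union <- outer(total, total, "+") - shared
  d <- (union - shared) / union
  d[union == 0] <- 0
  diag(d) <- 0
  d <- (d + t(d)) / 2
  dimnames(d) <- list(rownames(table), rownames(table))
  d
}

#' Principal coordinates analysis
#'
#' Gower double-centering of `-D^2/2` followed by eigendecomposition.
#' Coordinates are eigenvectors scaled by the square root of their (positive)
#' eigenvalues; negative eigenvalues are dropped without correction and
#' reported via a message. Proportions explained are over positive
#' eigenvalues only.
#'
#' @param dist Square symmetric distance matrix with zero diagonal.
#' @param tol Asymmetry tolerance (default 1e-8).
#' @return List with `coordinates`, `eigenvalues`, `proportion_explained`.
#' @export
pcoa <- function(dist, tol = 1e-8) {
  dist <- as.matrix(dist)
  if (nrow(dist) != ncol(dist)) stop("distance matrix must be square")
  if (max(abs(dist - t(dist))) > tol) stop("distance matrix asymmetric beyond tolerance")
  if (max(abs(diag(dist))) > tol) stop("distance matrix diagonal must be zero")
  n <- nrow(dist)
  A <- -0.5 * dist^2
  C <- diag(n) - matrix(1 / n, n, n)
  B <- C %*% A %*% C
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- e$values > max(abs(e$values)) * 1e-10
  if (any(e$values < -max(abs(e$values)) * 1e-10)) {
    message(sprintf("pcoa: dropped %d negative eigenvalue(s)",
                    sum(e$values < -max(abs(e$values)) * 1e-10)))
  }
  vals <- e$values[pos]
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(vals), nrow = length(vals))
  rownames(coords) <- rownames(dist)
  colnames(coords) <- paste0("PC", seq_along(vals))
  list(coordinates = coords, eigenvalues = vals,
       proportion_explained = vals / sum(vals))
}

#' Write a distance matrix as TSV
#'
#' @param dist Square matrix with dimnames.
#' @param path Output file.
#' @export
write_distance_tsv <- function(dist, path) {
  dt <- data.table::as.data.table(as.matrix(dist), keep.rownames = "sample_id")
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
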