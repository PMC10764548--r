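#' Jaccard dissimilarity between band profiles
#'
#' `d(A, B) = 1 - a / (a + b + c)` where `a` counts bands present in both
#' genotypes and `b`, `c` the mismatches, computed over pairwise-complete
#' bands; joint absences carry no information and are ignored. A pair with
#' no informative band (no band present in either profile, or no complete
#' band) gets `NA` and is flagged.
#'
#' @param bands 0/1 matrix (genotypes x bands), `NA` allowed.
#' @return Symmetric matrix of dissimilarities in \[0, 1\], zero diagonal;
#'   attribute `"flagged_pairs"` lists uninformative pairs.
#' @examples
#' b <- rbind(g1 = c(1, 1, 0, 1), g2 = c(1, 0, 1, 1))
#' jaccard_matrix(b)["g1", "g2"]  # 0.5
#' @export
jaccard_matrix <- function(bands) {
  B <- as.matrix(bands)
  if (nrow(B) < 2) stop("need >= 2 genotypes")
  bad <- which(!(B %in% c(0, 1, NA)))
  if (length(bad) > 0) stop("bands must be scored 0/1 (or NA)")
  n <- nrow(B)
  ids <- rownames(B)
  if (is.null(ids)) ids <- sprintf("G%03d", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  flagged <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(B[i, ]) & !is.na(B[j, ])
      a <- sum(B[i, ok] == 1 & B[j, ok] == 1)
      b <- sum(B[i, ok] == 1 & B[j, ok] == 0)
      cc <- sum(B[i, ok] == 0 & B[j, ok] == 1)
      if (a + b + cc == 0) {
        D[i, j] <- D[j, i] <- NA_real_
        flagged <- c(flagged, paste(ids[i], ids[j], sep = "|"))
      } else {
        D[i, j] <- D[j, i] <- 1 - a / (a + b + cc)
      }
    }
  }
  attr(D, "flagged_pairs") <- flagged
  D
}

#' Neighbor-joining tree from a dissimilarity matrix
#'
#' Classical Saitou-Nei agglomeration (equal taxon weights) via
#' \code{\link[ape]{nj}}; exact on additive (tree-metric) inputs. Taxa are
#' processed in lexicographic label order so the output is invariant to
#' input order up to isomorphism. Negative branch lengths (possible on
#' non-additive data) are clamped to zero and flagged.
#'
#' @param dm Symmetric dissimilarity matrix with labels.
#' @param clamp_negative Clamp negative branch lengths to 0 (default TRUE).
#' @return An [ape::phylo] tree; attribute `"n_negative_clamped"` counts
#'   clamped branches.
#' @export
neighbor_joining <- function(dm, clamp_negative = TRUE) {
  dm <- as.matrix(dm)
  if (anyNA(dm)) {
    stop("distance matrix has missing values: impute them or drop the ",
         "affected genotypes before tree building")
  }
  if (nrow(dm) < 3) stop("need >= 3 taxa")
  ord <- order(rownames(dm))
  dm <- dm[ord, ord]
  tree <- ape::nj(stats::as.dist(dm))
  n_neg <- sum(tree$edge.length < 0)
  if (clamp_negative && n_neg > 0) {
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  attr(tree, "n_negative_clamped") <- n_neg
  tree
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples band columns (the default resampling unit for dominant or
#' band-scored data) or whole loci with replacement, rebuilds the NJ tree
#' for each replicate, and records for every internal edge of the reference
#' tree the fraction of replicates containing the same bipartition.
#'
#' @param bands 0/1 band matrix (genotypes x bands).
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @param unit `"bands"` (default) resamples single columns; `"loci"`
#'   resamples groups of columns sharing the name prefix before `"."`.
#' @return List of class `nj_boot`: `tree` (reference NJ tree with node
#'   labels set to support fractions), `support` (per internal node),
#'   `n_reps`.
#' @export
bootstrap_support <- function(bands, n_reps = 1000, seed = 1,
                              unit = c("bands", "loci")) {
  unit <- match.arg(unit)
  if (n_reps < 1) stop("n_reps must be >= 1")
  B <- as.matrix(bands)
  ref <- neighbor_joining(jaccard_matrix(B))
  set.seed(as.integer(seed))
  groups <- if (unit == "loci") {
    split(seq_len(ncol(B)), sub("\\..*$", "", colnames(B)))
  } else as.list(seq_len(ncol(B)))
  boots <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    pick <- unlist(groups[sample.int(length(groups), replace = TRUE)],
                   use.names = FALSE)
    Db <- jaccard_matrix(B[, pick, drop = FALSE])
    if (anyNA(Db)) Db[is.na(Db)] <- 1  # uninformative resample: max distance
    boots[[r]] <- neighbor_joining(Db)
  }
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- counts / n_reps
  tree <- ref
  tree$node.label <- formatC(support, format = "f", digits = 3)
  tree$node.label[1] <- ""  # root pseudo-node of an unrooted tree
  structure(list(tree = tree, support = support, n_reps = n_reps),
            class = "nj_boot")
}

#' Duplicate genotypes in a distance matrix
#'
#' @param dm Dissimilarity matrix.
#' @param tol Distance at or below which two genotypes are duplicates.
#' @return Data frame `genotype1`, `genotype2`, `distance`.
#' @export
find_duplicates <- function(dm, tol = 0) {
  dm <- as.matrix(dm)
  idx <- which(upper.tri(dm) & !is.na(dm) & dm <= tol, arr.ind = TRUE)
  data.frame(genotype1 = rownames(dm)[idx[, 1]],
             genotype2 = colnames(dm)[idx[, 2]],
             distance = dm[idx], stringsAsFactors = FALSE)
}

#' Summary of pairwise dissimilarities
#'
#' @param dm Dissimilarity matrix.
#' @return List: `mean`, `sd`, `values` (upper-triangle vector), `histogram`
#'   (a [graphics::hist()]-style break/count list, computed without
#'   plotting).
#' @export
dissimilarity_summary <- function(dm) {
  v <- as.matrix(dm)[upper.tri(dm)]
  v <- v[!is.na(v)]
  h <- graphics::hist(v, breaks = seq(0, 1, by = 0.05), plot = FALSE)
  list(mean = mean(v), sd = stats::sd(v), values = v, histogram = h)
}
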