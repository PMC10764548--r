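#' Construct a marker panel of codominant SSR calls
#'
#' A `marker_panel` stores two allele-index matrices (`A1`, `A2`, genotypes x
#' loci, `NA` for missing calls) plus locus names, per-locus allele label
#' vectors, and an optional population assignment. A binary band-presence
#' view is derived on demand with [band_matrix()].
#'
#' @param A1,A2 Integer matrices (genotypes x loci) of allele indices
#'   (1-based within each locus); `NA` marks a missing call. Unordered:
#'   (a, b) and (b, a) are the same genotype.
#' @param genotypes Character vector of genotype ids.
#' @param loci Character vector of locus names.
#' @param allele_labels List (per locus) of character allele labels.
#' @param populations Optional factor/character of population assignments.
#' @return An object of class `marker_panel`.
#' @export
marker_panel <- function(A1, A2, genotypes = NULL, loci = NULL,
                         allele_labels = NULL, populations = NULL) {
  A1 <- as.matrix(A1); A2 <- as.matrix(A2)
  stopifnot(identical(dim(A1), dim(A2)))
  n <- nrow(A1); L <- ncol(A1)
  if (is.null(genotypes)) genotypes <- sprintf("G%03d", seq_len(n))
  if (is.null(loci)) loci <- sprintf("L%02d", seq_len(L))
  stopifnot(length(genotypes) == n, length(loci) == L)
  if (is.null(allele_labels)) {
    allele_labels <- lapply(seq_len(L), function(l) {
      a_max <- suppressWarnings(max(c(A1[, l], A2[, l]), na.rm = TRUE))
      if (!is.finite(a_max)) a_max <- 0L
      as.character(seq_len(max(a_max, 1L)))
    })
  }
  if (!is.null(populations)) {
    stopifnot(length(populations) == n)
    populations <- as.character(populations)
  }
  # canonical order: smaller allele index first (unordered genotypes)
  swap <- !is.na(A1) & !is.na(A2) & A1 > A2
  tmp <- A1[swap]; A1[swap] <- A2[swap]; A2[swap] <- tmp
  dimnames(A1) <- dimnames(A2) <- list(genotypes, loci)
  structure(list(A1 = A1, A2 = A2, genotypes = genotypes, loci = loci,
                 allele_labels = allele_labels, populations = populations),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("<marker_panel> %d genotypes x %d loci", length(x$genotypes),
              length(x$loci)))
  if (!is.null(x$populations)) {
    cat(sprintf(" (%d populations)", length(unique(x$populations))))
  }
  cat("\n")
  invisible(x)
}

#' Binary band-presence matrix of a marker panel
#'
#' Each allele of each locus becomes one band column (named
#' `locus.alleleLabel`); a cell is 1 when the genotype carries at least one
#' copy of that allele, 0 otherwise, `NA` when the locus call is missing.
#'
#' @param panel A [marker_panel()].
#' @return Integer matrix, genotypes x bands.
#' @export
band_matrix <- function(panel) {
  stopifnot(inherits(panel, "marker_panel"))
  n <- length(panel$genotypes)
  cols <- list()
  for (l in seq_along(panel$loci)) {
    labs <- panel$allele_labels[[l]]
    for (a in seq_along(labs)) {
      v <- as.integer((panel$A1[, l] == a) | (panel$A2[, l] == a))
      v[is.na(panel$A1[, l])] <- NA_integer_
      cols[[paste(panel$loci[l], labs[a], sep = ".")]] <- v
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- panel$genotypes
  out
}

#' Convert a band-presence matrix to codominant calls
#'
#' Bands are grouped into loci by the part of the column name before the
#' first `"."`. Per genotype and locus: one present band is read as a
#' homozygote, two bands as a heterozygote; more than two bands (possible in
#' pooled or polyploid data) are reduced to the two bands most frequent
#' panel-wide and the genotype is flagged. A locus with no present band is a
#' missing call.
#'
#' @param bands 0/1 matrix (genotypes x bands) with names `locus.allele`.
#' @param populations Optional population assignment.
#' @return A [marker_panel()]; genotypes reduced from >2 bands are listed in
#'   attribute `"flagged"` as `locus:genotype` strings.
#' @export
bands_to_panel <- function(bands, populations = NULL) {
  bands <- as.matrix(bands)
  if (is.null(colnames(bands))) {
    stop("band matrix must have 'locus.allele' column names")
  }
  ok <- matrix(bands %in% c(0L, 1L, NA), nrow(bands))
  if (any(!ok)) {
    bad <- arrayInd(which(!ok)[1], dim(bands))
    stop(sprintf("non-binary band entry at row %d, column %d",
                 bad[1, 1], bad[1, 2]))
  }
  locus_of <- sub("\\..*$", "", colnames(bands))
  allele_of <- sub("^[^.]*\\.", "", colnames(bands))
  loci <- unique(locus_of)
  n <- nrow(bands)
  geno <- rownames(bands)
  if (is.null(geno)) geno <- sprintf("G%03d", seq_len(n))
  A1 <- A2 <- matrix(NA_integer_, n, length(loci))
  labels <- vector("list", length(loci))
  flagged <- character(0)
  for (l in seq_along(loci)) {
    cols <- which(locus_of == loci[l])
    labels[[l]] <- allele_of[cols]
    freq <- colSums(bands[, cols, drop = FALSE], na.rm = TRUE)
    for (i in seq_len(n)) {
      present <- which(bands[i, cols] == 1L)
      if (length(present) == 0) next
      if (length(present) == 1) {
        A1[i, l] <- A2[i, l] <- present
      } else if (length(present) == 2) {
        A1[i, l] <- present[1]; A2[i, l] <- present[2]
      } else {
        keep <- present[order(-freq[present])][1:2]
        A1[i, l] <- min(keep); A2[i, l] <- max(keep)
        flagged <- c(flagged, paste(loci[l], geno[i], sep = ":"))
      }
    }
  }
  out <- marker_panel(A1, A2, genotypes = geno, loci = loci,
                      allele_labels = labels, populations = populations)
  attr(out, "flagged") <- flagged
  out
}

#' Simulate an SSR marker panel from diverged sub-populations
#'
#' Ancestral allele frequencies are drawn per locus from a flat Dirichlet;
#' sub-population frequencies diverge from them by Balding-Nichols Dirichlet
#' draws with concentration `p * (1 - Fst) / Fst` (Fst = 0 means identical
#' frequencies). Individual admixture proportions `Q` are Dirichlet
#' (`admixture_alpha`) draws (hard balanced assignment when the
#' concentration is 0). Each allele copy picks an origin population from `Q`
#' and an allele from that population's frequencies; with probability
#' `inbreeding_F` a locus is autozygous and the single drawn copy is
#' duplicated, emulating selfing.
#'
#' @param config A [panel_config()].
#' @return A list with `panel` (a [marker_panel()] whose `populations` are
#'   the true max-Q assignments) and `truth` (`Q`, `allele_freqs` as a list
#'   pop -> locus -> frequency vector, `ancestral_freqs`, and the `config`).
#' @examples
#' sim <- simulate_markers(panel_config(seed = 1))
#' dim(sim$panel$A1)
#' @export
simulate_markers <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  set.seed(substream_seed(config$seed, 2L))
  n <- config$n_genotypes
  L <- config$n_loci
  K <- config$K_true
  if (any(config$alleles_per_locus < 2) && config$target_Fst > 0) {
    stop("degenerate allele count: polymorphism requested at a locus with < 2 alleles")
  }

  anc <- lapply(seq_len(L), function(l) {
    a <- config$alleles_per_locus[l]
    # moderately skewed ancestral frequencies, bounded away from 0
    p <- rdirichlet_one(rep(1.5, a))
    p <- (p + 0.05 / a) / (1 + 0.05)
    p / sum(p)
  })
  Fst <- config$target_Fst
  P <- lapply(seq_len(K), function(k) {
    lapply(seq_len(L), function(l) {
      p <- anc[[l]]
      if (Fst <= 0 || length(p) == 1) return(p)
      rdirichlet_one(p * (1 - Fst) / Fst)
    })
  })

  if (config$admixture_alpha == 0 || K == 1) {
    pop_of <- rep_len(seq_len(K), n)
    Q <- matrix(0, n, K)
    Q[cbind(seq_len(n), pop_of)] <- 1
  } else {
    Q <- t(vapply(seq_len(n), function(i) {
      rdirichlet_one(rep(config$admixture_alpha, K))
    }, numeric(K)))
  }

  A1 <- A2 <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) {
    auto <- stats::runif(L) < config$inbreeding_F
    for (l in seq_len(L)) {
      z1 <- sample.int(K, 1, prob = Q[i, ])
      a1 <- sample.int(length(anc[[l]]), 1, prob = P[[z1]][[l]])
      if (auto[l]) {
        a2 <- a1
      } else {
        z2 <- sample.int(K, 1, prob = Q[i, ])
        a2 <- sample.int(length(anc[[l]]), 1, prob = P[[z2]][[l]])
      }
      A1[i, l] <- a1; A2[i, l] <- a2
    }
  }
  geno_ids <- sprintf("G%03d", seq_len(n))
  loci <- sprintf("SSR%02d", seq_len(L))
  labels <- lapply(config$alleles_per_locus, function(a) sprintf("%02d", seq_len(a)))
  pops <- sprintf("Pop%d", max.col(Q, ties.method = "first"))
  panel <- marker_panel(A1, A2, genotypes = geno_ids, loci = loci,
                        allele_labels = labels, populations = pops)
  truth <- list(Q = Q, allele_freqs = P, ancestral_freqs = anc, config = config)
  list(panel = panel, truth = truth)
}

rdirichlet_one <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}
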