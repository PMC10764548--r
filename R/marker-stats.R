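#' Per-locus allele frequencies
#'
#' Counts allele copies over the scored (non-missing) codominant calls,
#' overall and per population when assignments are present. Alleles below
#' `pool_threshold` can optionally be merged into one synthetic `"pooled"`
#' class (the accommodation some population-genetics formats require).
#'
#' @param panel A [marker_panel()].
#' @param pool_threshold Frequency at or below which alleles are pooled;
#'   `NULL` (default) disables pooling.
#' @param by_population Also return per-population frequencies.
#' @return List of class `allele_freqs`: `total` (list locus -> named
#'   frequency vector), `by_pop` (list pop -> locus -> vector, or `NULL`),
#'   `n_scored` (genotypes scored per locus), `excluded` (loci with no
#'   scored call).
#' @export
allele_frequencies <- function(panel, pool_threshold = NULL,
                               by_population = !is.null(panel$populations)) {
  stopifnot(inherits(panel, "marker_panel"))
  L <- length(panel$loci)
  count1 <- function(rows, l) {
    a <- c(panel$A1[rows, l], panel$A2[rows, l])
    a <- a[!is.na(a)]
    labs <- panel$allele_labels[[l]]
    cnt <- tabulate(a, length(labs))
    names(cnt) <- labs
    cnt
  }
  freqs_of <- function(rows) {
    lapply(seq_len(L), function(l) {
      cnt <- count1(rows, l)
      if (sum(cnt) == 0) return(NULL)
      p <- cnt / sum(cnt)
      if (!is.null(pool_threshold)) p <- pool_freqs(p, pool_threshold)
      p
    })
  }
  all_rows <- seq_along(panel$genotypes)
  total <- freqs_of(all_rows)
  names(total) <- panel$loci
  excluded <- panel$loci[vapply(total, is.null, logical(1))]
  if (length(excluded) > 0) {
    warning("loci with all calls missing excluded: ",
            paste(excluded, collapse = ", "))
  }
  by_pop <- NULL
  if (by_population && !is.null(panel$populations)) {
    by_pop <- lapply(split(all_rows, panel$populations), function(rows) {
      f <- freqs_of(rows); names(f) <- panel$loci; f
    })
  }
  n_scored <- vapply(seq_len(L), function(l) sum(!is.na(panel$A1[, l])),
                     integer(1))
  names(n_scored) <- panel$loci
  structure(list(total = total, by_pop = by_pop, n_scored = n_scored,
                 excluded = excluded), class = "allele_freqs")
}

# merge alleles at frequency <= threshold into one "pooled" class
pool_freqs <- function(p, threshold) {
  low <- p <= threshold & p > 0
  if (sum(low) < 2) return(p)
  kept <- p[!low]
  c(kept, pooled = sum(p[low]))
}

#' Per-locus diversity statistics for an SSR panel
#'
#' For each locus: observed allele count (`Na`), effective allele count
#' (`Ne = 1 / sum(p^2)`), Shannon information (`I = -sum(p * ln p)`, nats),
#' observed heterozygosity (`Ho`, fraction of heterozygous calls), Nei
#' diversity (`He = 1 - sum(p^2)`), polymorphism information content by the
#' frequency form `PIC = 1 - sum(p^2)` plus a genotypic-class variant
#' (`PIC_genotypic`, same formula on genotype-pattern frequencies),
#' discriminating power by the confusion-probability formula
#' `D = 1 - sum(g_i * (N * g_i - 1) / (N - 1))` over genotype-pattern
#' frequencies `g_i`, and the count of rare alleles (frequency <=
#' `rare_threshold`). The identity `He = 1 - 1/Ne` holds by construction.
#'
#' @param panel A [marker_panel()].
#' @param freqs Optional precomputed [allele_frequencies()] result.
#' @param rare_threshold Rare-allele frequency cut-off (default 0.05).
#' @return Data frame with one row per scored locus.
#' @examples
#' sim <- simulate_markers(panel_config(seed = 3))
#' locus_diversity(sim$panel)
#' @export
locus_diversity <- function(panel, freqs = NULL, rare_threshold = 0.05) {
  stopifnot(inherits(panel, "marker_panel"))
  if (is.null(freqs)) freqs <- allele_frequencies(panel, by_population = FALSE)
  rows <- list()
  for (l in seq_along(panel$loci)) {
    p <- freqs$total[[l]]
    if (is.null(p)) next
    p_pos <- p[p > 0]
    Na <- length(p_pos)
    sum_p2 <- sum(p^2)
    Ne <- 1 / sum_p2
    He <- 1 - sum_p2
    I <- -sum(p_pos * log(p_pos))
    a1 <- panel$A1[, l]; a2 <- panel$A2[, l]
    scored <- !is.na(a1)
    N <- sum(scored)
    Ho <- if (N > 0) mean(a1[scored] != a2[scored]) else NA_real_
    # genotype-pattern frequencies for D and the genotypic PIC variant
    pat <- paste(a1[scored], a2[scored], sep = "/")
    g <- as.numeric(table(pat)) / N
    D <- if (N > 1) 1 - sum(g * (N * g - 1) / (N - 1)) else NA_real_
    rows[[length(rows) + 1]] <- data.frame(
      locus = panel$loci[l], n = N, Na = Na, Ne = Ne, I = I, Ho = Ho,
      He = He, PIC = 1 - sum_p2, PIC_genotypic = 1 - sum(g^2), D = D,
      rare_alleles = sum(p_pos <= rare_threshold),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Private alleles per population
#'
#' An allele is private to a population when it is observed there and in no
#' other population.
#'
#' @param panel A [marker_panel()] with population assignments (or supply
#'   `populations`).
#' @param populations Optional population labels overriding the panel's.
#' @return Data frame: `population`, `locus`, `allele`, `carriers`
#'   (comma-separated genotype ids), plus a per-population `count` summary
#'   in attribute `"counts"`. Zero rows (with a warning) when fewer than 2
#'   populations are present.
#' @export
private_alleles <- function(panel, populations = NULL) {
  stopifnot(inherits(panel, "marker_panel"))
  pops <- if (!is.null(populations)) as.character(populations) else panel$populations
  if (is.null(pops)) stop("no population assignment available")
  upop <- unique(pops)
  empty <- data.frame(population = character(0), locus = character(0),
                      allele = character(0), carriers = character(0),
                      stringsAsFactors = FALSE)
  if (length(upop) < 2) {
    warning("fewer than 2 populations: no private alleles defined")
    attr(empty, "counts") <- stats::setNames(integer(length(upop)), upop)
    return(empty)
  }
  rows <- list()
  for (l in seq_along(panel$loci)) {
    labs <- panel$allele_labels[[l]]
    seen <- matrix(FALSE, length(upop), length(labs),
                   dimnames = list(upop, labs))
    for (pp in upop) {
      idx <- which(pops == pp)
      a <- c(panel$A1[idx, l], panel$A2[idx, l])
      a <- unique(a[!is.na(a)])
      seen[pp, a] <- TRUE
    }
    n_pops_with <- colSums(seen)
    priv <- which(n_pops_with == 1)
    for (a in priv) {
      pp <- upop[which(seen[, a])]
      idx <- which(pops == pp)
      carriers <- panel$genotypes[idx][
        (panel$A1[idx, l] %in% a) | (panel$A2[idx, l] %in% a)]
      carriers <- carriers[!is.na(carriers)]
      rows[[length(rows) + 1]] <- data.frame(
        population = pp, locus = panel$loci[l], allele = labs[a],
        carriers = paste(carriers, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else empty
  counts <- stats::setNames(integer(length(upop)), upop)
  if (nrow(out) > 0) {
    tb <- table(out$population)
    counts[names(tb)] <- as.integer(tb)
  }
  attr(out, "counts") <- counts
  out
}
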