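#' Bin genotype means into phenotypic classes
#'
#' Min--max scales the values to \[0, 100\] and cuts them into `n_classes`
#' equal-width classes (half-open on the right, last class closed), the
#' standard preparation for Shannon-Weaver phenotypic diversity. When all
#' values are identical every genotype falls in a single class.
#'
#' @param values Numeric vector of genotype means for one trait (or a BLUP
#'   table data frame together with `trait`).
#' @param trait Trait column name when `values` is a data frame.
#' @param n_classes Number of classes (default 10).
#' @return List with `class` (integer class 1..n per genotype), `freqs`
#'   (class proportions, length `n_classes`), `breaks`, and the value
#'   `range`.
#' @export
bin_blups <- function(values, trait = NULL, n_classes = 10) {
  if (is.data.frame(values)) {
    stopifnot(!is.null(trait), trait %in% names(values))
    values <- values[[trait]]
  }
  v <- values[is.finite(values)]
  if (length(v) == 0) stop("no finite values to bin")
  rng <- range(v)
  if (diff(rng) == 0) {
    cls <- rep(1L, length(values))
    cls[!is.finite(values)] <- NA_integer_
    freqs <- c(1, rep(0, n_classes - 1))
    return(list(class = cls, freqs = freqs,
                breaks = seq(0, 100, length.out = n_classes + 1), range = rng))
  }
  scaled <- (values - rng[1]) / diff(rng) * 100
  cls <- pmin(floor(scaled / (100 / n_classes)) + 1L, n_classes)
  cls[!is.finite(values)] <- NA_integer_
  freqs <- tabulate(cls, n_classes) / sum(!is.na(cls))
  list(class = as.integer(cls), freqs = freqs,
       breaks = seq(0, 100, length.out = n_classes + 1), range = rng)
}

#' Shannon-Weaver diversity of phenotypic class frequencies
#'
#' `H = -sum(Pi * log2(Pi))` over the non-empty classes, and the normalized
#' `H' = H / log2(n_occupied)` where `n_occupied` is the number of occupied
#' classes, so `H'` is 1 exactly when the occupied classes are equifrequent.
#' `H'` is 0 when a single class is occupied. The diversity category is
#' `"high"` when `H' >= 0.60`, `"intermediate"` when `0.40 <= H' < 0.60`,
#' and `"low"` when `H' < 0.40`.
#'
#' @param freqs Non-negative class frequencies; renormalized to sum to 1
#'   (integer percentages are accepted).
#' @return List with `H` (bits), `H_prime`, `n_occupied`, `category`.
#' @examples
#' shannon_index(c(2, 60, 38))  # H ~ 1.10, H' ~ 0.69
#' @export
shannon_index <- function(freqs) {
  if (length(freqs) == 0) stop("empty frequency vector")
  if (any(freqs < 0)) stop("frequencies must be non-negative")
  s <- sum(freqs)
  if (s <= 0) stop("frequencies sum to zero")
  p <- freqs / s
  p_occ <- p[p > 0]
  n_occ <- length(p_occ)
  H <- -sum(p_occ * log2(p_occ))  # 0 * log 0 contributes 0
  H_prime <- if (n_occ >= 2) H / log2(n_occ) else 0
  category <- if (H_prime >= 0.60) "high" else
    if (H_prime >= 0.40) "intermediate" else "low"
  list(H = H, H_prime = H_prime, n_occupied = n_occ, category = category)
}

#' Per-trait phenotypic diversity profile
#'
#' Bins each trait's genotype means into phenotypic classes and computes the
#' Shannon-Weaver diversity: the per-trait analog of a germplasm diversity
#' table (value range, class frequencies, H, H', category).
#'
#' @param blups BLUP table data frame (first column `genotype`).
#' @param traits Trait columns (default: all but `genotype`).
#' @param n_classes Number of phenotypic classes.
#' @return Data frame with one row per trait: `trait`, `min`, `max`,
#'   `class_1` ... `class_n` (percent), `n_occupied`, `H`, `H_prime`,
#'   `category`.
#' @export
diversity_profile <- function(blups, traits = NULL, n_classes = 10) {
  if (is.null(traits)) traits <- setdiff(names(blups), "genotype")
  rows <- lapply(traits, function(tr) {
    b <- bin_blups(blups[[tr]], n_classes = n_classes)
    s <- shannon_index(b$freqs)
    out <- data.frame(trait = tr, min = b$range[1], max = b$range[2],
                      stringsAsFactors = FALSE)
    fr <- as.list(100 * b$freqs)
    names(fr) <- sprintf("class_%d", seq_len(n_classes))
    cbind(out, as.data.frame(fr),
          data.frame(n_occupied = s$n_occupied, H = s$H,
                     H_prime = s$H_prime, category = s$category,
                     stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}
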