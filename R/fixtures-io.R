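#' Write a fixture set for a simulated panel
#'
#' Writes the field book (`field_book.csv`), the codominant genotype table
#' (`codominant.csv`, cells `"a/b"`), the binary band matrix (`bands.csv`)
#' and, when ground truth is supplied, a `ground_truth.json` sidecar.
#' Re-reading with [read_fixture_set()] reproduces the objects exactly.
#'
#' @param trial Field-book data frame as returned by [simulate_trial()].
#' @param panel A [marker_panel()].
#' @param path Directory to write into (created if needed).
#' @param truth Optional list of ground-truth parameters to record.
#' @return Invisibly, the vector of files written.
#' @export
write_fixture_set <- function(trial, panel, path, truth = NULL) {
  if (is.null(trial) || nrow(trial) == 0 || is.null(panel) ||
      length(panel$genotypes) == 0) {
    stop("empty panel: nothing to write")
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create output directory: ", path)
  files <- character(0)

  f <- file.path(path, "field_book.csv")
  utils::write.csv(trial, f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)

  f <- file.path(path, "codominant.csv")
  utils::write.csv(codominant_table(panel), f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)

  f <- file.path(path, "bands.csv")
  bm <- band_matrix(panel)
  utils::write.csv(data.frame(genotype = rownames(bm), bm,
                              check.names = FALSE, stringsAsFactors = FALSE),
                   f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)

  if (!is.null(truth)) {
    f <- file.path(path, "ground_truth.json")
    tr <- truth
    tr$config <- unclass(tr$config)
    jsonlite::write_json(tr, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, f)
  }
  invisible(files)
}

#' Codominant genotype table of a marker panel
#'
#' @param panel A [marker_panel()].
#' @return Data frame: `genotype`, optional `population`, then one `"a/b"`
#'   character column per locus (`"-/-"` for a missing call).
#' @export
codominant_table <- function(panel) {
  stopifnot(inherits(panel, "marker_panel"))
  out <- data.frame(genotype = panel$genotypes, stringsAsFactors = FALSE)
  if (!is.null(panel$populations)) out$population <- panel$populations
  for (l in seq_along(panel$loci)) {
    labs <- panel$allele_labels[[l]]
    a1 <- labs[panel$A1[, l]]
    a2 <- labs[panel$A2[, l]]
    cell <- paste(a1, a2, sep = "/")
    cell[is.na(panel$A1[, l])] <- "-/-"
    out[[panel$loci[l]]] <- cell
  }
  out
}

#' Read a fixture set written by [write_fixture_set()]
#'
#' @param path Directory containing the fixture files.
#' @return List with `trial`, `panel`, and `truth` (`NULL` when no sidecar).
#' @export
read_fixture_set <- function(path) {
  trial <- read_field_book(file.path(path, "field_book.csv"))
  panel <- read_codominant(file.path(path, "codominant.csv"))
  gt <- file.path(path, "ground_truth.json")
  truth <- if (file.exists(gt)) jsonlite::read_json(gt, simplifyVector = TRUE) else NULL
  list(trial = trial, panel = panel, truth = truth)
}

#' Read a plot-level field book
#'
#' Expects columns `genotype`, `rep`, `block`, then numeric trait columns.
#' Duplicate genotype entries within a replicate are an error; genotypes
#' missing from some replicate are accepted (unbalanced data).
#'
#' @param file Path to a delimited text file (comma-separated).
#' @return Field-book data frame.
#' @export
read_field_book <- function(file) {
  fb <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("genotype", "rep", "block")
  if (!all(need %in% names(fb))) {
    stop("field book must have columns: ", paste(need, collapse = ", "))
  }
  key <- paste(fb$genotype, fb$rep, fb$block)
  if (anyDuplicated(key)) {
    stop("duplicate genotype within a replicate block at row ",
         which(duplicated(key))[1])
  }
  traits <- setdiff(names(fb), need)
  for (tr in traits) {
    if (!is.numeric(fb[[tr]])) {
      suppressWarnings(v <- as.numeric(fb[[tr]]))
      if (any(is.na(v) & !is.na(fb[[tr]]) & fb[[tr]] != "")) {
        stop("non-numeric value in trait column '", tr, "'")
      }
      fb[[tr]] <- v
    }
  }
  fb
}

#' Read a codominant genotype table
#'
#' GenAlEx-like layout: a `genotype` column, an optional `population`
#' column, then one column per locus with `"allele1/allele2"` cells
#' (`"-/-"` or empty for missing).
#'
#' @param file Path to a comma-separated file.
#' @return A [marker_panel()].
#' @export
read_codominant <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  if (!"genotype" %in% names(df)) stop("codominant table needs a 'genotype' column")
  pops <- if ("population" %in% names(df)) df$population else NULL
  loci <- setdiff(names(df), c("genotype", "population"))
  if (length(loci) == 0) stop("codominant table has no locus columns")
  n <- nrow(df)
  A1 <- A2 <- matrix(NA_integer_, n, length(loci))
  labels <- vector("list", length(loci))
  for (l in seq_along(loci)) {
    cells <- df[[loci[l]]]
    parts <- strsplit(cells, "/", fixed = TRUE)
    bad <- which(lengths(parts) != 2 & !(cells %in% c("", "-/-", NA)))
    if (length(bad) > 0) {
      stop("malformed allele pair '", cells[bad[1]], "' at row ", bad[1],
           ", locus ", loci[l])
    }
    a1 <- vapply(parts, function(p) if (length(p) == 2) p[1] else NA_character_, "")
    a2 <- vapply(parts, function(p) if (length(p) == 2) p[2] else NA_character_, "")
    a1[a1 == "-"] <- NA; a2[a2 == "-"] <- NA
    labs <- sort(unique(stats::na.omit(c(a1, a2))))
    if (length(labs) == 0) labs <- "1"
    labels[[l]] <- labs
    A1[, l] <- match(a1, labs)
    A2[, l] <- match(a2, labs)
  }
  marker_panel(A1, A2, genotypes = df$genotype, loci = loci,
               allele_labels = labels, populations = pops)
}

#' Read a binary band matrix
#'
#' @param file Comma-separated file with a `genotype` column and 0/1 band
#'   columns named `locus.allele`.
#' @return A [marker_panel()] (via [bands_to_panel()]).
#' @export
read_band_matrix <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"genotype" %in% names(df)) stop("band matrix needs a 'genotype' column")
  m <- as.matrix(df[, setdiff(names(df), "genotype"), drop = FALSE])
  rownames(m) <- df$genotype
  ok <- matrix(m %in% c(0, 1, NA), nrow(m))
  if (any(!ok)) {
    bad <- arrayInd(which(!ok)[1], dim(m))
    stop(sprintf("non-binary band cell '%s' at row %d, column '%s'",
                 m[bad[1, 1], bad[1, 2]], bad[1, 1],
                 colnames(m)[bad[1, 2]]))
  }
  storage.mode(m) <- "integer"
  bands_to_panel(m)
}
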