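# Synthetic dominant-AFLP data: parental allele-frequency models, admixed
# genotype simulation, fragment elimination, missing data, and the marker
# filter applied to the real matrix (drop markers with > 5% missing).

#' Construct an AFLP presence/absence matrix object
#'
#' @param values integer matrix, individuals x markers, entries 0 (band
#'   absent), 1 (band present) or NA (missing). Dimnames supply individual
#'   and marker identifiers; defaults are generated when absent.
#' @param ploidy_scored ploidy at which individuals are scored (default 2:
#'   all individuals are treated as diploid, as their karyotypes look).
#' @return object of class \code{aflp_matrix} (an integer matrix with
#'   attributes).
#' @export
aflp_matrix <- function(values, ploidy_scored = 2L) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  bad <- !(values %in% c(0L, 1L)) & !is.na(values)
  if (any(bad)) stop("AFLP values must be 0, 1 or missing (NA)")
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("ind%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("M%03d", seq_len(ncol(values)))
  }
  structure(values, ploidy_scored = as.integer(ploidy_scored),
            class = c("aflp_matrix", "matrix", "array"))
}

#' @export
print.aflp_matrix <- function(x, ...) {
  cat("AFLP matrix:", nrow(x), "individuals x", ncol(x), "markers;",
      sum(is.na(x)), "missing cells; scored at ploidy",
      attr(x, "ploidy_scored"), "\n")
  invisible(x)
}

#' Sample parental population allele frequencies
#'
#' Draws per-marker presence-allele frequencies for K differentiated
#' parental populations under a Balding-Nichols model: an ancestral
#' frequency per marker from Uniform(0.05, 0.95), then per-population
#' frequencies from Beta(p_anc (1-F)/F, (1-p_anc)(1-F)/F) with F equal to
#' \code{divergence}. Larger F spreads populations further from the
#' ancestral value; as F tends to 0 all populations collapse onto it.
#'
#' @param K number of parental populations (>= 1).
#' @param L number of dominant markers.
#' @param divergence differentiation parameter F in (0, 1).
#' @param seed integer seed.
#' @return object of class \code{population_model}: list with \code{K},
#'   \code{L}, \code{p} (K x L frequency matrix in [0,1]) and
#'   \code{p_ancestral}.
#' @export
sample_parental_frequencies <- function(K, L, divergence, seed) {
  K <- as.integer(K); L <- as.integer(L)
  if (K < 1L || L < 1L) stop("K and L must be >= 1")
  if (!is.finite(divergence) || divergence <= 0 || divergence >= 1) {
    stop("divergence must lie strictly in (0, 1)")
  }
  set.seed(seed)
  p_anc <- stats::runif(L, 0.05, 0.95)
  scale <- (1 - divergence) / divergence
  p <- matrix(NA_real_, K, L,
              dimnames = list(sprintf("pop%d", seq_len(K)),
                              sprintf("M%03d", seq_len(L))))
  for (k in seq_len(K)) {
    p[k, ] <- stats::rbeta(L, p_anc * scale, (1 - p_anc) * scale)
  }
  structure(list(K = K, L = L, p = p, p_ancestral = p_anc,
                 divergence = divergence),
            class = "population_model")
}

#' True-ancestry container
#'
#' @param Q_true numeric matrix, individuals x K, rows summing to 1 within
#'   1e-9: the true admixture proportions used by the generator.
#' @param copy_number optional integer vector (or single value) of per-
#'   individual allele-copy numbers; defaults to diploid scoring downstream.
#' @return object of class \code{true_ancestry}.
#' @export
true_ancestry <- function(Q_true, copy_number = NULL) {
  Q_true <- as.matrix(Q_true)
  rs <- rowSums(Q_true)
  if (any(abs(rs - 1) > 1e-9)) stop("Q_true rows must sum to 1")
  if (any(Q_true < 0)) stop("Q_true entries must be non-negative")
  if (is.null(rownames(Q_true))) {
    rownames(Q_true) <- sprintf("ind%02d", seq_len(nrow(Q_true)))
  }
  structure(list(Q_true = Q_true, copy_number = copy_number),
            class = "true_ancestry")
}

#' Simulate a dominant AFLP matrix from a population model and ancestry
#'
#' For individual i at marker l, each of its c allele copies independently
#' takes ancestry k with probability Q_true[i, k] and is a presence allele
#' with probability p[k, l]; the band is scored 1 iff at least one copy is
#' a presence allele. By default c = \code{ploidy_scored} (2): individuals
#' are scored diploid whatever their real ploidy, as in the karyotype-based
#' scoring decision. Supplying \code{copy_number} in the ancestry enables
#' copy-number-aware banding for sensitivity analysis.
#'
#' @param model a \code{\link{sample_parental_frequencies}} output.
#' @param ancestry a \code{\link{true_ancestry}}.
#' @param seed integer seed.
#' @param ploidy_scored default allele-copy count per individual (2).
#' @return an \code{\link{aflp_matrix}}.
#' @export
simulate_matrix <- function(model, ancestry, seed, ploidy_scored = 2L) {
  stopifnot(inherits(model, "population_model"),
            inherits(ancestry, "true_ancestry"))
  Q <- ancestry$Q_true
  if (ncol(Q) != model$K) stop("ancestry K does not match model K")
  N <- nrow(Q); L <- model$L
  cn <- ancestry$copy_number
  if (is.null(cn)) cn <- rep(as.integer(ploidy_scored), N)
  if (length(cn) == 1L) cn <- rep(as.integer(cn), N)
  set.seed(seed)
  # P(copy is a presence allele) marginalized over its ancestry:
  # pi[i, l] = sum_k Q[i, k] p[k, l]; band = 1 - (all c copies null)
  pi_il <- Q %*% model$p
  vals <- matrix(0L, N, L, dimnames = list(rownames(Q), colnames(model$p)))
  for (i in seq_len(N)) {
    nulls <- stats::rbinom(L, cn[i], 1 - pi_il[i, ])
    vals[i, ] <- as.integer(nulls < cn[i])
  }
  aflp_matrix(vals, ploidy_scored = ploidy_scored)
}

#' Unidirectional fragment elimination
#'
#' Allopolyploid genomes may lose restriction fragments from one parental
#' genome only. This zeroes the eliminated parent's presence-allele
#' frequency at a random subset of round(fraction * L) markers, leaving the
#' other parents untouched, so hybrid-derived lineages sampled from the
#' modified model lack that parent's bands at those markers.
#'
#' @param model a \code{population_model}.
#' @param fraction fraction of markers affected, in [0, 1].
#' @param eliminated_parent population index whose fragments are lost.
#' @param seed integer seed.
#' @return the modified \code{population_model}, with an
#'   \code{eliminated_markers} field naming the affected markers.
#' @export
apply_fragment_elimination <- function(model, fraction, eliminated_parent,
                                       seed) {
  stopifnot(inherits(model, "population_model"))
  if (!is.finite(fraction) || fraction < 0 || fraction > 1) {
    stop("fraction must lie in [0, 1]")
  }
  eliminated_parent <- as.integer(eliminated_parent)
  if (eliminated_parent < 1L || eliminated_parent > model$K) {
    stop("invalid parent index: ", eliminated_parent)
  }
  n_drop <- round(fraction * model$L)
  set.seed(seed)
  idx <- if (n_drop > 0) sort(sample.int(model$L, n_drop)) else integer(0)
  model$p[eliminated_parent, idx] <- 0
  model$eliminated_markers <- colnames(model$p)[idx]
  model$eliminated_parent <- eliminated_parent
  model
}

#' Inject missing data completely at random
#'
#' @param matrix an \code{\link{aflp_matrix}}.
#' @param rate per-cell missingness probability in [0, 1).
#' @param seed integer seed.
#' @return the matrix with cells independently set to NA.
#' @export
inject_missing <- function(matrix, rate, seed) {
  stopifnot(inherits(matrix, "aflp_matrix"))
  if (!is.finite(rate) || rate < 0 || rate >= 1) {
    stop("rate must lie in [0, 1)")
  }
  if (rate == 0) return(matrix)
  set.seed(seed)
  miss <- stats::runif(length(matrix)) < rate
  matrix[miss] <- NA_integer_
  matrix
}

#' Filter markers by missing-data fraction
#'
#' Markers with more than \code{max_missing} missing data are removed;
#' a marker at exactly the threshold is retained (the rule drops strictly
#' greater fractions).
#'
#' @param matrix an \code{\link{aflp_matrix}}.
#' @param max_missing maximum tolerated missing fraction (default 0.05).
#' @return the filtered \code{aflp_matrix}.
#' @export
filter_markers <- function(matrix, max_missing = 0.05) {
  stopifnot(inherits(matrix, "aflp_matrix"))
  frac <- colMeans(is.na(matrix))
  keep <- frac <= max_missing
  aflp_matrix(unclass(matrix)[, keep, drop = FALSE],
              ploidy_scored = attr(matrix, "ploidy_scored"))
}

#' Read / write dominant marker matrices
#'
#' Two dialects are supported. \code{csv}: individuals x markers with a
#' header row and row names, missing as NA. \code{structure}: one row per
#' individual (dominant data, diploid-scored individuals on a single line),
#' whitespace-separated, first column the individual identifier, optional
#' second column a population code, missing encoded as -9.
#'
#' @param path file path.
#' @param format \code{"csv"} or \code{"structure"}.
#' @rdname aflp_io
#' @return \code{read_matrix}: an \code{\link{aflp_matrix}} (with a
#'   \code{pop} attribute when the STRUCTURE file carries a population
#'   column). \code{write_matrix}: the path, invisibly.
#' @export
read_matrix <- function(path, format = c("csv", "structure")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    return(aflp_matrix(as.matrix(df)))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[[1]])[[1]] + 1L
    stop("ragged STRUCTURE file: row ", bad, " has ", widths[bad - 1L],
         " fields, expected ", widths[[1]])
  }
  n_meta <- widths[[1]] - length(header)
  if (!n_meta %in% c(1L, 2L)) {
    stop("STRUCTURE rows must carry the marker columns plus an individual ",
         "id and optionally a population code")
  }
  ids <- vapply(rows, `[[`, character(1), 1L)
  pop <- if (n_meta == 2L) vapply(rows, `[[`, character(1), 2L) else NULL
  vals <- t(vapply(rows, function(r) {
    v <- suppressWarnings(as.integer(r[-seq_len(n_meta)]))
    v[v == -9L] <- NA_integer_
    v
  }, integer(length(header))))
  dimnames(vals) <- list(ids, header)
  out <- aflp_matrix(vals)
  attr(out, "pop") <- pop
  out
}

#' @param matrix an \code{\link{aflp_matrix}}.
#' @param pop optional per-individual population codes for the STRUCTURE
#'   dialect.
#' @rdname aflp_io
#' @export
write_matrix <- function(matrix, path, format = c("csv", "structure"),
                         pop = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(matrix, "aflp_matrix"))
  if (format == "csv") {
    utils::write.csv(as.data.frame(unclass(matrix)), path)
    return(invisible(path))
  }
  vals <- unclass(matrix)
  vals[is.na(vals)] <- -9L
  header <- paste(colnames(matrix), collapse = " ")
  meta <- rownames(matrix)
  if (!is.null(pop)) meta <- paste(meta, pop)
  body <- paste(meta, apply(vals, 1, paste, collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Study-shaped synthetic AFLP fixture
#'
#' Generates a dataset with the structure of the Moroccan \emph{Clonopsis}
#' AFLP matrix: 4 parental populations, dominant diploid-scored markers,
#' a mix of pure and admixed (50/50 hybrid) individuals, 2% missing data
#' injected before the 5%-missing marker filter, and enough markers that
#' about 195 survive filtering.
#'
#' @param n_pure pure individuals per population (default 5; 4 x 5 = 20).
#' @param n_hybrid admixed individuals (default 7, giving 27 in total).
#' @param L markers generated before filtering (default 200).
#' @param K parental populations (default 4).
#' @param divergence Balding-Nichols F (default 0.25).
#' @param missing_rate pre-filter missingness (default 0.02).
#' @param seed integer seed.
#' @return list with \code{matrix} (filtered \code{aflp_matrix}),
#'   \code{raw} (pre-filter matrix), \code{model}, \code{ancestry} and
#'   \code{pop} (true population label, "admixed" for hybrids).
#' @export
synth_aflp_preset <- function(n_pure = 5L, n_hybrid = 7L, L = 200L, K = 4L,
                              divergence = 0.25, missing_rate = 0.02,
                              seed = 3L) {
  model <- sample_parental_frequencies(K, L, divergence, seed = seed)
  Q <- matrix(0, n_pure * K + n_hybrid, K)
  pop <- character(nrow(Q))
  for (k in seq_len(K)) {
    rows <- (k - 1L) * n_pure + seq_len(n_pure)
    Q[rows, k] <- 1
    pop[rows] <- sprintf("pop%d", k)
  }
  if (n_hybrid > 0) {
    hrows <- n_pure * K + seq_len(n_hybrid)
    # 50/50 hybrids between consecutive population pairs, cycling
    pair <- cbind(((seq_len(n_hybrid) - 1L) %% K) + 1L,
                  (seq_len(n_hybrid) %% K) + 1L)
    for (j in seq_len(n_hybrid)) Q[hrows[j], pair[j, ]] <- 0.5
    pop[hrows] <- "admixed"
  }
  rownames(Q) <- sprintf("ind%02d", seq_len(nrow(Q)))
  anc <- true_ancestry(Q)
  raw <- simulate_matrix(model, anc, seed = seed + 1L)
  raw <- inject_missing(raw, missing_rate, seed = seed + 2L)
  list(matrix = filter_markers(raw), raw = raw, model = model,
       ancestry = anc, pop = pop)
}
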