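# Maximum-likelihood admixture inference for dominant, diploid-scored
# markers. The model is the classic admixture model: individual i draws
# each of its two allele copies at marker l from source population k with
# probability Q[i, k]; a copy from population k carries the presence allele
# with probability p[k, l]; the band is seen iff at least one copy is a
# presence allele, so P(band) = 1 - (1 - pi)^2 with pi = sum_k Q[i,k] p[k,l].
# Fitting is by EM over the latent per-copy (ancestry, allele) states, with
# closed-form E- and M-steps, so the log-likelihood is monotone.

derive_seed <- function(seed, offset) {
  # deterministic 31-bit sub-stream seed
  as.integer((as.double(seed) %% 65536) * 31627 + offset) %% 2147483647L
}

#' Fit the admixture model to a dominant AFLP matrix
#'
#' Maximizes sum_il log P(band_il | Q_i, p) with
#' P(band) = 1 - (1 - pi_il)^2, pi_il = sum_k Q_ik p_kl, by EM from
#' \code{n_init} random starts; the best start (highest log-likelihood) is
#' returned. Missing cells are skipped in the likelihood. For K = 1 the
#' maximum-likelihood solution is the closed form
#' p_l = 1 - sqrt(1 - f_l) (f_l the observed band frequency), which EM
#' reaches from that starting point immediately.
#'
#' @param matrix an \code{\link{aflp_matrix}} (0/1/NA).
#' @param K number of source populations, 1 <= K <= number of individuals.
#' @param seed integer seed driving the random starts.
#' @param n_init number of random EM starts (default 5).
#' @param max_iter iteration cap per start (default 2000).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @return object of class \code{admixture_result}: list with \code{Q}
#'   (individuals x K, rows sum to 1), \code{p_hat} (K x L in [0,1]),
#'   \code{loglik}, \code{K}, \code{replicate_logliks} (one per start),
#'   \code{n_iter} and \code{converged}.
#' @examples
#' syn <- synth_aflp_preset(seed = 3)
#' res <- fit_admixture(syn$matrix, K = 4, seed = 1, n_init = 3)
#' head(res$Q)
#' @export
fit_admixture <- function(matrix, K, seed, n_init = 5L, max_iter = 2000L,
                          tol = 1e-8) {
  stopifnot(inherits(matrix, "aflp_matrix"))
  K <- as.integer(K)
  Y <- unclass(matrix)
  N <- nrow(Y); L <- ncol(Y)
  if (N < 1L || L < 1L) stop("matrix must be non-empty")
  if (K < 1L || K > N) stop("K must lie in [1, number of individuals]")
  if (any(colSums(!is.na(Y)) == 0L)) {
    stop("all-missing marker present; apply filter_markers() first")
  }
  f_obs <- colMeans(Y == 1L, na.rm = TRUE)
  p1 <- 1 - sqrt(pmax(0, 1 - f_obs))      # K = 1 closed-form MLE
  best <- NULL
  rep_ll <- numeric(n_init)
  for (s in seq_len(n_init)) {
    set.seed(derive_seed(seed, s))
    if (K == 1L) {
      Q0 <- matrix(1, N, 1L)
      P0 <- matrix(pmin(pmax(p1, 1e-9), 1 - 1e-9), 1L, L)
    } else {
      # Dirichlet(1) membership rows; allele frequencies anchored on the
      # pooled closed-form estimate, perturbed per cluster
      g <- matrix(stats::rgamma(N * K, 1), N, K)
      Q0 <- g / rowSums(g)
      P0 <- matrix(pmin(pmax(rep(p1, each = K) +
                               stats::runif(K * L, -0.3, 0.3),
                             0.02), 0.98), K, L)
    }
    run <- em_dominant(Y, Q0, P0, max_iter = max_iter, tol = tol)
    rep_ll[s] <- run$loglik
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  dimnames(best$Q) <- list(rownames(Y), sprintf("cluster%d", seq_len(K)))
  dimnames(best$P) <- list(sprintf("cluster%d", seq_len(K)), colnames(Y))
  structure(list(Q = best$Q, p_hat = best$P, loglik = best$loglik, K = K,
                 replicate_logliks = rep_ll, n_iter = best$n_iter,
                 converged = best$converged),
            class = "admixture_result")
}

#' @export
print.admixture_result <- function(x, ...) {
  cat("Admixture fit: K =", x$K, "| loglik =", format(x$loglik),
      "|", nrow(x$Q), "individuals,", ncol(x$p_hat), "markers |",
      x$n_iter, "EM iterations",
      if (x$converged) "(converged)" else "(iteration cap)", "\n")
  invisible(x)
}

# EM core. Y: N x L integer with NA; Q0: N x K; P0: K x L.
em_dominant <- function(Y, Q0, P0, max_iter, tol) {
  N <- nrow(Y); L <- ncol(Y); K <- nrow(P0)
  obs <- !is.na(Y)
  y1 <- obs & Y == 1L
  y0 <- obs & Y == 0L
  n_obs <- rowSums(obs)                    # observed loci per individual
  Q <- Q0; P <- P0
  ll_old <- -Inf
  n_iter <- 0L; converged <- FALSE
  for (it in seq_len(max_iter)) {
    n_iter <- it
    B <- Q %*% (1 - P)                     # P(one copy is a null allele)
    B <- pmin(pmax(B, 1e-12), 1 - 1e-12)
    ll <- sum(log(1 - B[y1]^2)) + 2 * sum(log(B[y0]))
    if (ll < ll_old - 1e-6 * (1 + abs(ll_old))) {
      stop("EM log-likelihood decreased: ", ll_old, " -> ", ll)
    }
    done <- is.finite(ll_old) && abs(ll - ll_old) <= tol * (1 + abs(ll_old))
    ll_old <- ll
    if (done) { converged <- TRUE; break }
    # E-step accumulators: expected ancestry-k copy counts and presence
    # counts per (i, k) and per (k, l)
    w1 <- matrix(0, N, L); w1[y1] <- 1 / (1 - B[y1]^2)
    w1b <- matrix(0, N, L); w1b[y1] <- 1 / (1 + B[y1])
    w0 <- matrix(0, N, L); w0[y0] <- 1 / B[y0]
    Enew_Q <- matrix(0, N, K)
    Xkl <- matrix(0, K, L)
    Ekl <- matrix(0, K, L)
    for (k in seq_len(K)) {
      a_k <- outer(Q[, k], P[k, ])         # copy from k, presence allele
      b_k <- outer(Q[, k], 1 - P[k, ])     # copy from k, null allele
      x_k <- 2 * a_k * w1                  # expected presence copies
      e_k <- x_k + 2 * b_k * w1b + 2 * b_k * w0
      Enew_Q[, k] <- rowSums(e_k)
      Xkl[k, ] <- colSums(x_k)
      Ekl[k, ] <- colSums(e_k)
    }
    Q <- Enew_Q / (2 * n_obs)
    Q <- Q / rowSums(Q)                    # guard rounding drift
    Pnew <- Xkl / Ekl
    Pnew[!is.finite(Pnew)] <- P[!is.finite(Pnew)]   # cluster empty at locus
    P <- pmin(pmax(Pnew, 1e-9), 1 - 1e-9)
  }
  list(Q = Q, P = P, loglik = ll_old, n_iter = n_iter, converged = converged)
}

#' Select the number of source populations K
#'
#' Runs \code{\link{fit_admixture}} once per (K, replicate) pair, each
#' replicate a single independent random start, and selects K two ways:
#' \describe{
#'   \item{max_prob}{the mean log-likelihood rule with a plateau guard,
#'     applied to the complexity-adjusted mean log-likelihood
#'     L(K) - d_K, where d_K = N (K - 1) + K L is the free parameter count
#'     (an AIC-type adjustment): the smallest K whose adjusted mean lies
#'     within one standard error of the maximum. The adjustment is needed
#'     because the raw maximum-likelihood surface is non-decreasing in K
#'     (nested models), so it has no plateau; the Bayesian estimated
#'     probability of data that this rule emulates is penalized for model
#'     complexity implicitly.}
#'   \item{deltaK}{Evanno's second-order statistic
#'     |L(K+1) - 2 L(K) + L(K-1)| / sd(L(K)), defined only at interior
#'     grid values with >= 3 replicates; the K maximizing it is chosen.}
#' }
#'
#' @param matrix an \code{\link{aflp_matrix}}.
#' @param K_grid contiguous integer vector of K values (e.g. 1:8).
#' @param replicates fits per K (default 5).
#' @param seed integer seed.
#' @return object of class \code{k_selection}: list with \code{K_grid},
#'   \code{loglik} (replicates x K matrix), \code{mean_loglik},
#'   \code{adj_loglik} (complexity-adjusted mean), \code{sd_loglik},
#'   \code{deltaK} (NA at the grid endpoints),
#'   \code{chosen_K_max_prob}, \code{chosen_K_deltaK} and \code{chosen_K}
#'   (the agreed value when the two methods coincide; on disagreement the
#'   deltaK choice is preferred — the second-order signal is robust to the
#'   monotone rise of the likelihood in K, which is what defeats
#'   likelihood-level rules — with the disagreement recorded in
#'   \code{agreement}).
#' @export
select_K <- function(matrix, K_grid = 1:8, replicates = 5L, seed = 1L) {
  K_grid <- as.integer(K_grid)
  if (length(K_grid) < 2L || any(diff(K_grid) != 1L)) {
    stop("K_grid must be a contiguous increasing integer grid")
  }
  if (replicates < 3L) stop("deltaK needs >= 3 replicates per K")
  ll <- matrix(NA_real_, replicates, length(K_grid),
               dimnames = list(NULL, paste0("K", K_grid)))
  for (j in seq_along(K_grid)) {
    for (r in seq_len(replicates)) {
      fitr <- fit_admixture(matrix, K_grid[j],
                            seed = derive_seed(seed, j * 1000L + r),
                            n_init = 1L)
      ll[r, j] <- fitr$loglik
    }
  }
  mean_ll <- colMeans(ll)
  sd_ll <- apply(ll, 2, stats::sd)
  # complexity adjustment: d_K free parameters (Q rows and p table); the
  # raw ML loglik is monotone in K, the adjusted surface has a plateau
  d_K <- nrow(matrix) * (K_grid - 1) + K_grid * ncol(matrix)
  adj_ll <- mean_ll - d_K
  # plateau / one-standard-error rule on the adjusted surface
  jmax <- which.max(adj_ll)
  se <- sd_ll[jmax] / sqrt(replicates)
  chosen_max_prob <- K_grid[min(which(adj_ll >= adj_ll[jmax] - se))]
  # Evanno deltaK over interior grid points (a linear-in-K penalty cancels
  # in the second difference, so raw and adjusted means give the same value)
  deltaK <- rep(NA_real_, length(K_grid))
  for (j in seq_along(K_grid)[-c(1, length(K_grid))]) {
    deltaK[j] <- abs(mean_ll[j + 1] - 2 * mean_ll[j] + mean_ll[j - 1]) /
      sd_ll[j]
  }
  chosen_deltaK <- if (all(is.na(deltaK))) NA_integer_ else
    K_grid[which.max(deltaK)]
  agreement <- isTRUE(chosen_max_prob == chosen_deltaK)
  chosen <- if (agreement || is.na(chosen_deltaK)) chosen_max_prob else
    chosen_deltaK
  structure(list(K_grid = K_grid, loglik = ll, mean_loglik = mean_ll,
                 adj_loglik = adj_ll, sd_loglik = sd_ll, deltaK = deltaK,
                 chosen_K_max_prob = chosen_max_prob,
                 chosen_K_deltaK = chosen_deltaK,
                 chosen_K = chosen, agreement = agreement),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  tab <- data.frame(K = x$K_grid, mean_loglik = x$mean_loglik,
                    adj_loglik = x$adj_loglik, sd = x$sd_loglik,
                    deltaK = x$deltaK)
  print(tab, row.names = FALSE)
  cat("chosen K:", x$chosen_K_max_prob, "(mean-likelihood plateau),",
      x$chosen_K_deltaK, "(Evanno deltaK)\n")
  invisible(x)
}

#' Assign individuals to populations by the q >= threshold rule
#'
#' An individual is assigned to its arg-max cluster iff its largest
#' membership coefficient reaches the threshold (inclusive); otherwise it
#' is flagged admixed, i.e. of mixed parental ancestry.
#'
#' @param result an \code{admixture_result}.
#' @param threshold membership cutoff in (0.5, 1]; default 0.80.
#' @return data.frame with columns \code{individual}, \code{max_q},
#'   \code{cluster} (arg-max index) and \code{assignment} (cluster name or
#'   \code{"admixed"}).
#' @export
assign_individuals <- function(result, threshold = 0.80) {
  stopifnot(inherits(result, "admixture_result"))
  if (threshold <= 0.5 || threshold > 1) {
    stop("threshold must lie in (0.5, 1]")
  }
  Q <- result$Q
  max_q <- apply(Q, 1, max)
  cl <- apply(Q, 1, which.max)
  data.frame(individual = rownames(Q), max_q = max_q, cluster = cl,
             assignment = ifelse(max_q >= threshold,
                                 colnames(Q)[cl], "admixed"),
             row.names = NULL, stringsAsFactors = FALSE)
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_permutations(n - 1L)) {
      out[[length(out) + 1L]] <- c(i, ifelse(p >= i, p + 1L, p))
    }
  }
  out
}

#' Align cluster labels between two admixture fits
#'
#' Cluster labels are arbitrary (label switching), so replicate fits must
#' be permuted onto a reference before comparison. The permutation of the
#' other fit's clusters minimizing the total L1 distance between the
#' allele-frequency tables is applied to both its Q and p_hat (exhaustive
#' search for K <= 8, greedy matching above).
#'
#' @param reference,other \code{admixture_result} objects with equal K.
#' @return \code{other}, relabelled.
#' @export
align_labels <- function(reference, other) {
  stopifnot(inherits(reference, "admixture_result"),
            inherits(other, "admixture_result"))
  K <- reference$K
  if (other$K != K) stop("K mismatch: ", K, " vs ", other$K)
  D <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    D[i, j] <- sum(abs(reference$p_hat[i, ] - other$p_hat[j, ]))
  }
  if (K <= 8L) {
    perms <- all_permutations(K)
    costs <- vapply(perms, function(pm) sum(D[cbind(seq_len(K), pm)]),
                    numeric(1))
    perm <- perms[[which.min(costs)]]
  } else {
    perm <- integer(K); taken <- rep(FALSE, K)
    for (i in order(apply(D, 1, min))) {
      j <- order(D[i, ])[!taken[order(D[i, ])]][1]
      perm[i] <- j; taken[j] <- TRUE
    }
  }
  other$Q <- other$Q[, perm, drop = FALSE]
  other$p_hat <- other$p_hat[perm, , drop = FALSE]
  colnames(other$Q) <- colnames(reference$Q)
  rownames(other$p_hat) <- rownames(reference$p_hat)
  other
}

#' Align an estimated Q matrix to a known truth
#'
#' Convenience for recovery experiments: permutes the columns of an
#' estimated Q to minimize the total L1 distance to a true Q matrix.
#'
#' @param Q_hat,Q_true matrices with equal dimensions.
#' @return the permuted \code{Q_hat}.
#' @export
align_Q_to_truth <- function(Q_hat, Q_true) {
  K <- ncol(Q_true)
  stopifnot(ncol(Q_hat) == K, nrow(Q_hat) == nrow(Q_true))
  D <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    D[i, j] <- sum(abs(Q_true[, i] - Q_hat[, j]))
  }
  perms <- if (K <= 8L) all_permutations(K) else list(seq_len(K))
  costs <- vapply(perms, function(pm) sum(D[cbind(seq_len(K), pm)]),
                  numeric(1))
  Q_hat[, perms[[which.min(costs)]], drop = FALSE]
}

#' Forced K = 2 analysis without an outgroup
#'
#' Re-analysis mode for detecting admixed genotypes: drop the listed
#' individuals (typically a divergent outgroup whose presence dominates the
#' first split), fit K = 2 with several replicates, align the replicates,
#' and return the consensus membership matrix with q >= 0.80 assignments.
#'
#' @param matrix an \code{\link{aflp_matrix}}.
#' @param exclude character vector of individual identifiers to drop (may
#'   be empty).
#' @param replicates number of replicate fits (default 10).
#' @param seed integer seed.
#' @param threshold assignment cutoff (default 0.80).
#' @return list with \code{result} (consensus \code{admixture_result}),
#'   \code{assignments} (from \code{\link{assign_individuals}}) and
#'   \code{replicate_logliks}.
#' @export
forced_K2_analysis <- function(matrix, exclude = character(0),
                               replicates = 10L, seed = 1L,
                               threshold = 0.80) {
  stopifnot(inherits(matrix, "aflp_matrix"))
  exclude <- as.character(exclude)
  unknown <- setdiff(exclude, rownames(matrix))
  if (length(unknown)) stop("unknown individuals: ",
                            paste(unknown, collapse = ", "))
  keep <- setdiff(rownames(matrix), exclude)
  if (length(keep) < 2L) stop("exclusion leaves fewer than 2 individuals")
  sub <- aflp_matrix(unclass(matrix)[keep, , drop = FALSE],
                     ploidy_scored = attr(matrix, "ploidy_scored"))
  keep_l <- colSums(!is.na(sub)) > 0L      # drop any now-all-missing marker
  sub <- aflp_matrix(unclass(sub)[, keep_l, drop = FALSE],
                     ploidy_scored = attr(matrix, "ploidy_scored"))
  fits <- lapply(seq_len(replicates), function(r) {
    fit_admixture(sub, K = 2L, seed = derive_seed(seed, 7000L + r),
                  n_init = 1L)
  })
  lls <- vapply(fits, `[[`, numeric(1), "loglik")
  ref <- fits[[which.max(lls)]]
  aligned <- lapply(fits, align_labels, reference = ref)
  Qbar <- Reduce(`+`, lapply(aligned, `[[`, "Q")) / replicates
  Qbar <- Qbar / rowSums(Qbar)
  consensus <- ref
  consensus$Q <- Qbar
  consensus$replicate_logliks <- lls
  list(result = consensus, assignments = assign_individuals(consensus,
                                                            threshold),
       replicate_logliks = lls)
}
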