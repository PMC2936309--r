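# End-to-end pipeline: origin scenario -> triploid meiosis -> synthetic
# dominant AFLP matrix -> marker filter -> admixture inference -> report.

#' Default pipeline configuration
#'
#' Returns the study-shaped default configuration: an intermediate triploid
#' female (n = 18 trivalents), a 4-population dominant-marker generator
#' (divergence 0.25, 2% missingness, 5% missing-marker filter) and an
#' admixture stage scanning K = 1..8 with 5 replicates and the q >= 0.80
#' assignment rule.
#'
#' @param seed master seed (mandatory for a run).
#' @param out_dir output directory (created on demand).
#' @return nested configuration list understood by \code{\link{run_pipeline}}.
#' @export
default_config <- function(seed = 1L, out_dir = tempfile("clonosim_run_")) {
  list(
    seed = seed,
    out_dir = out_dir,
    meiosis = list(n_trivalents = 18L, n_eggs = 100000L),
    generator = list(K = 4L, L = 200L, divergence = 0.25,
                     n_pure = 5L, n_hybrid = 7L,
                     missing_rate = 0.02, max_missing = 0.05,
                     elimination_fraction = 0, eliminated_parent = 1L),
    inference = list(K_min = 1L, K_max = 8L, replicates = 5L,
                     threshold = 0.80)
  )
}

validate_config <- function(config) {
  if (is.null(config$seed)) stop("config error: a master seed is mandatory")
  m <- config$meiosis; g <- config$generator; inf <- config$inference
  if (is.null(m$n_eggs) || m$n_eggs < 1) {
    stop("config error [meiosis]: n_eggs must be >= 1")
  }
  if (is.null(m$n_trivalents) || m$n_trivalents < 1) {
    stop("config error [meiosis]: n_trivalents must be >= 1")
  }
  if (g$divergence <= 0 || g$divergence >= 1) {
    stop("config error [generator]: divergence must lie in (0, 1)")
  }
  if (g$missing_rate < 0 || g$missing_rate >= 1) {
    stop("config error [generator]: missing_rate must lie in [0, 1)")
  }
  if (inf$K_min < 1 || inf$K_max < inf$K_min) {
    stop("config error [inference]: bad K grid")
  }
  invisible(TRUE)
}

#' Read a pipeline configuration from YAML
#'
#' Fields missing from the file fall back to \code{\link{default_config}}.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  config <- default_config(seed = user$seed %||% NULL)
  for (top in intersect(names(user), names(config))) {
    if (is.list(config[[top]])) {
      for (f in names(user[[top]])) config[[top]][[f]] <- user[[top]][[f]]
    } else {
      config[[top]] <- user[[top]]
    }
  }
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full scenario-to-report pipeline
#'
#' Stages, each seeded from a deterministic sub-stream of the master seed:
#' (1) meiosis of the intermediate triploid female: exact egg-class
#' distribution plus Monte-Carlo frequencies; (2) synthetic dominant AFLP
#' generation from differentiated parental populations with pure and
#' admixed individuals, optional unidirectional fragment elimination, and
#' missing-data injection; (3) the missing-marker filter; (4) admixture
#' inference: K selection over the configured grid and q-threshold
#' assignment at the chosen K. All outputs are written as CSV/JSON to
#' \code{config$out_dir}; re-running with an identical configuration
#' reproduces identical files.
#'
#' @param config configuration list (see \code{\link{default_config}}) or a
#'   path to a YAML file.
#' @return (invisibly) list with \code{meiosis}, \code{matrix},
#'   \code{model}, \code{ancestry}, \code{k_selection}, \code{fit},
#'   \code{assignments}, \code{distances} and \code{files}.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  seed <- config$seed
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("clonosim pipeline | master seed %d", seed),
                 sprintf("R %s | clonosim %s", getRversion(),
                         as.character(utils::packageVersion("clonosim"))))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_lines <<- c(log_lines, sprintf("stage %-10s ok (%.2fs)", name,
                                       proc.time()[["elapsed"]] - t0))
    res
  }

  m <- config$meiosis
  meiosis <- stage("meiosis", meiosis_report(m$n_trivalents, m$n_eggs,
                                             seed = derive_seed(seed, 1L)))

  g <- config$generator
  synth <- stage("generate", {
    model <- sample_parental_frequencies(g$K, g$L, g$divergence,
                                         seed = derive_seed(seed, 2L))
    if (g$elimination_fraction > 0) {
      model <- apply_fragment_elimination(model, g$elimination_fraction,
                                          g$eliminated_parent,
                                          seed = derive_seed(seed, 3L))
    }
    n_ind <- g$n_pure * g$K + g$n_hybrid
    Q <- matrix(0, n_ind, g$K)
    pop <- character(n_ind)
    for (k in seq_len(g$K)) {
      rows <- (k - 1L) * g$n_pure + seq_len(g$n_pure)
      Q[rows, k] <- 1
      pop[rows] <- sprintf("pop%d", k)
    }
    if (g$n_hybrid > 0) {
      hr <- g$n_pure * g$K + seq_len(g$n_hybrid)
      pair <- cbind(((seq_len(g$n_hybrid) - 1L) %% g$K) + 1L,
                    (seq_len(g$n_hybrid) %% g$K) + 1L)
      for (j in seq_len(g$n_hybrid)) Q[hr[j], pair[j, ]] <- 0.5
      pop[hr] <- "admixed"
    }
    rownames(Q) <- sprintf("ind%02d", seq_len(n_ind))
    anc <- true_ancestry(Q)
    raw <- simulate_matrix(model, anc, seed = derive_seed(seed, 4L))
    raw <- inject_missing(raw, g$missing_rate, seed = derive_seed(seed, 5L))
    list(model = model, ancestry = anc, raw = raw, pop = pop)
  })

  filtered <- stage("filter", filter_markers(synth$raw, g$max_missing))

  inf <- config$inference
  ks <- stage("select_K", select_K(filtered, inf$K_min:inf$K_max,
                                   replicates = inf$replicates,
                                   seed = derive_seed(seed, 6L)))
  fit <- stage("fit", fit_admixture(filtered, ks$chosen_K,
                                    seed = derive_seed(seed, 7L),
                                    n_init = inf$replicates))
  assignments <- assign_individuals(fit, inf$threshold)
  assignments$true_pop <- synth$pop
  dists <- stage("distances", jaccard_distance(filtered))

  files <- c(
    meiosis = file.path(out_dir, "egg_distribution.csv"),
    matrix = file.path(out_dir, "aflp_filtered.csv"),
    raw = file.path(out_dir, "aflp_raw.csv"),
    q = file.path(out_dir, "Q.csv"),
    p = file.path(out_dir, "p_hat.csv"),
    kselect = file.path(out_dir, "k_selection.json"),
    assign = file.path(out_dir, "assignments.csv"),
    dist = file.path(out_dir, "jaccard.csv"),
    log = file.path(out_dir, "run_log.txt")
  )
  utils::write.csv(meiosis, files["meiosis"], row.names = FALSE)
  write_matrix(filtered, files["matrix"], "csv")
  write_matrix(synth$raw, files["raw"], "csv")
  utils::write.csv(as.data.frame(fit$Q), files["q"])
  utils::write.csv(as.data.frame(fit$p_hat), files["p"])
  jsonlite::write_json(
    list(K_grid = ks$K_grid, mean_loglik = ks$mean_loglik,
         adj_loglik = ks$adj_loglik, sd_loglik = ks$sd_loglik,
         deltaK = ks$deltaK,
         chosen_K_max_prob = ks$chosen_K_max_prob,
         chosen_K_deltaK = ks$chosen_K_deltaK, agreement = ks$agreement),
    files["kselect"], auto_unbox = TRUE, digits = NA, na = "null")
  utils::write.csv(assignments, files["assign"], row.names = FALSE)
  utils::write.csv(as.data.frame(dists), files["dist"])
  writeLines(log_lines, files["log"])

  invisible(list(meiosis = meiosis, matrix = filtered, model = synth$model,
                 ancestry = synth$ancestry, k_selection = ks, fit = fit,
                 assignments = assignments, distances = dists,
                 files = files, config = config))
}

#' Pairwise Jaccard distances between band profiles
#'
#' d(i, j) = 1 - (shared bands) / (bands present in either individual),
#' computed over markers co-scored in both individuals (missing cells are
#' excluded pairwise). A pair with no band present at any co-scored marker
#' has distance 1, with a warning.
#'
#' @param matrix an \code{\link{aflp_matrix}} with >= 2 individuals.
#' @return symmetric numeric matrix with zero diagonal, entries in [0, 1].
#' @export
jaccard_distance <- function(matrix) {
  stopifnot(inherits(matrix, "aflp_matrix"))
  Y <- unclass(matrix)
  N <- nrow(Y)
  if (N < 2L) stop("need at least 2 individuals")
  D <- matrix(0, N, N, dimnames = list(rownames(Y), rownames(Y)))
  warned <- FALSE
  for (i in seq_len(N - 1L)) for (j in (i + 1L):N) {
    ok <- !is.na(Y[i, ]) & !is.na(Y[j, ])
    a <- Y[i, ok]; b <- Y[j, ok]
    union <- sum(a == 1L | b == 1L)
    if (union == 0L) {
      warned <- TRUE
      d <- 1
    } else {
      d <- 1 - sum(a == 1L & b == 1L) / union
    }
    D[i, j] <- D[j, i] <- d
  }
  if (warned) warning("pair(s) with no co-scored present band: distance 1")
  D
}
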