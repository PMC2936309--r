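#' Trivalent segregation pattern
#'
#' At meiosis I of a triploid female each homologous group forms a trivalent
#' that segregates 2<->1: two chromosomes to one pole, the third to the
#' opposite pole. A pattern records, per trivalent, whether the doubled
#' complement is delivered to the oocyte-II pole.
#'
#' @param to_oocyte_two logical vector, one flag per trivalent; TRUE means
#'   this trivalent sends its doubled complement to the oocyte II.
#' @return object of class \code{segregation_pattern}.
#' @export
segregation_pattern <- function(to_oocyte_two) {
  to_oocyte_two <- as.logical(to_oocyte_two)
  if (length(to_oocyte_two) < 1L || anyNA(to_oocyte_two)) {
    stop("to_oocyte_two must be a non-empty logical vector without NA")
  }
  structure(list(to_oocyte_two = to_oocyte_two,
                 n_trivalents = length(to_oocyte_two)),
            class = "segregation_pattern")
}

#' Exact distribution of doubled complements reaching the oocyte pole
#'
#' With each trivalent orienting independently and fairly (probability 1/2
#' per pole), the number m of doubled complements delivered to the
#' oocyte-II pole is Binomial(n_trivalents, 1/2).
#'
#' @param n_trivalents number of trivalents (18 in \emph{Clonopsis}).
#' @return named numeric vector of probabilities for m = 0..n_trivalents;
#'   masses sum to 1.
#' @examples
#' exact_m_distribution(18)[["9"]]  # 0.18547, the scheme-B egg class
#' @export
exact_m_distribution <- function(n_trivalents) {
  n_trivalents <- as.integer(n_trivalents)
  if (is.na(n_trivalents) || n_trivalents < 1L) {
    stop("n_trivalents must be a positive integer")
  }
  m <- 0:n_trivalents
  stats::setNames(stats::dbinom(m, n_trivalents, 0.5), m)
}

#' Probability of the scheme-A (fully concordant) segregation
#'
#' Scheme A: all trivalents segregate concordantly, so that one meiotic
#' product receives two complete chromosome series and the other receives
#' one. Both concordant orientations (m = 0 and m = n) produce such a
#' product, hence the probability is 2 * (1/2)^n. For n = 18 this is
#' 7.63e-6, i.e. 7.63e-4 percent of eggs.
#'
#' @param n_trivalents number of trivalents.
#' @return probability in [0, 1].
#' @export
prob_scheme_A <- function(n_trivalents) {
  n_trivalents <- as.integer(n_trivalents)
  if (is.na(n_trivalents) || n_trivalents < 1L) {
    stop("n_trivalents must be a positive integer")
  }
  2 * 0.5^n_trivalents
}

#' Probability of the scheme-B (half-and-half) segregation
#'
#' Scheme B: exactly half of the trivalents deliver doubled complements to
#' the oocyte II and half deliver single chromosomes. For n = 18 this is
#' 0.18547 (18.5 percent of eggs).
#'
#' @param n_trivalents even number of trivalents.
#' @return probability in [0, 1].
#' @export
prob_scheme_B <- function(n_trivalents) {
  n_trivalents <- as.integer(n_trivalents)
  if (is.na(n_trivalents) || n_trivalents < 2L || n_trivalents %% 2L != 0L) {
    stop("n_trivalents must be an even integer >= 2")
  }
  unname(exact_m_distribution(n_trivalents)[as.character(n_trivalents / 2L)])
}

#' Segregate a triploid complement at meiosis I
#'
#' Applies a 2<->1 segregation pattern to a triploid source: the oocyte-II
#' pole receives 2 copies of each trivalent flagged TRUE and 1 copy of each
#' flagged FALSE, giving a pre-restitution oocyte with cn = n + m.
#'
#' @param pattern a \code{\link{segregation_pattern}}.
#' @param source triploid \code{\link{karyotype}} (default: uniform x3 with
#'   as many groups as the pattern has trivalents).
#' @return the oocyte-II \code{\link{karyotype}}.
#' @export
segregate <- function(pattern, source = NULL) {
  stopifnot(inherits(pattern, "segregation_pattern"))
  if (is.null(source)) {
    source <- karyotype(3L, n_groups = pattern$n_trivalents)
  }
  stopifnot(inherits(source, "karyotype"))
  if (source$n_groups != pattern$n_trivalents) {
    stop("pattern length (", pattern$n_trivalents,
         ") does not match the number of groups (", source$n_groups, ")")
  }
  if (!all(source$group_copies == 3L)) {
    stop("segregate requires a triploid source (3 copies per group)")
  }
  karyotype(ifelse(pattern$to_oocyte_two, 2L, 1L),
            n_groups = source$n_groups, x_group = source$x_group)
}

#' Apply anaphasic restitution to an oocyte
#'
#' Anaphasic restitution (retention of the second polar body) doubles every
#' chromosome of the oocyte-II complement, so each group's copy count
#' becomes even and the karyotype acquires a paired, diploid look whatever
#' its actual ploidy.
#'
#' @param oocyte a \code{\link{karyotype}}.
#' @return an egg object (class \code{egg}) with fields \code{karyotype},
#'   \code{restitution_applied} and \code{egg_class}.
#' @export
apply_restitution <- function(oocyte) {
  stopifnot(inherits(oocyte, "karyotype"))
  k <- karyotype(2L * oocyte$group_copies, n_groups = oocyte$n_groups,
                 x_group = oocyte$x_group)
  egg <- structure(list(karyotype = k, restitution_applied = TRUE,
                        egg_class = NA_character_), class = "egg")
  egg$egg_class <- classify_egg(egg)
  egg
}

#' @export
print.egg <- function(x, ...) {
  cat("Egg: cn =", total_cn(x$karyotype), "| class =", x$egg_class,
      "| restitution =", x$restitution_applied, "\n")
  invisible(x)
}

#' Classify an egg karyotype
#'
#' Maps an egg's copy-number profile to the named outcome classes of the
#' triploid-female meiosis model: cn = 72 uniformly x4 (the
#' \emph{C. soumiae}-like tetraploid), cn = 54 with half the groups x4 and
#' half x2 (the \emph{C. gallica}-like class), cn = 36 uniformly x2
#' (diploid-like, the never-discussed m = 0 outcome), the cn = 35 male
#' profile (all autosomes x2, single X), and any other aneuploid.
#'
#' @param egg an egg object or a \code{\link{karyotype}}.
#' @return one of \code{"soumiae_like"}, \code{"gallica_like"},
#'   \code{"diploid_like"}, \code{"male_35_like"}, \code{"other_aneuploid"}.
#' @export
classify_egg <- function(egg) {
  k <- if (inherits(egg, "egg")) egg$karyotype else egg
  stopifnot(inherits(k, "karyotype"))
  gc <- k$group_copies
  n <- k$n_groups
  half <- n %/% 2L
  auto <- gc[-k$x_group]
  if (all(gc == 4L)) return("soumiae_like")
  if (n %% 2L == 0L && sum(gc == 4L) == half && sum(gc == 2L) == half) {
    return("gallica_like")
  }
  if (all(gc == 2L)) return("diploid_like")
  if (all(auto == 2L) && gc[k$x_group] == 1L) return("male_35_like")
  "other_aneuploid"
}

#' Monte-Carlo simulation of triploid-female eggs
#'
#' Draws \code{n_eggs} independent uniformly random segregation patterns,
#' applies 2<->1 segregation and anaphasic restitution to each, and
#' tabulates the resulting egg classes.
#'
#' @param n_trivalents number of trivalents (18 in \emph{Clonopsis}).
#' @param n_eggs number of eggs to simulate.
#' @param seed integer seed; results are reproducible given the seed.
#' @param keep_eggs return the individual egg objects (memory-heavy for
#'   large \code{n_eggs}; default FALSE keeps only per-egg m and class).
#' @return list with \code{freq} (named class frequencies summing to 1),
#'   \code{counts}, \code{m} (per-egg doubled-complement count) and, when
#'   requested, \code{eggs}.
#' @examples
#' sim <- simulate_eggs(18, 1e4, seed = 1)
#' sim$freq["gallica_like"]  # close to 0.18547
#' @export
simulate_eggs <- function(n_trivalents, n_eggs, seed, keep_eggs = FALSE) {
  n_trivalents <- as.integer(n_trivalents)
  n_eggs <- as.integer(n_eggs)
  if (is.na(n_eggs) || n_eggs < 1L) stop("n_eggs must be >= 1")
  if (is.na(n_trivalents) || n_trivalents < 1L) {
    stop("n_trivalents must be >= 1")
  }
  set.seed(seed)
  # each egg's pattern is n_trivalents fair coin flips; m = number TRUE
  m <- stats::rbinom(n_eggs, n_trivalents, 0.5)
  cls <- m_to_class(m, n_trivalents)
  counts <- table(factor(cls, levels = egg_class_levels()))
  eggs <- NULL
  if (keep_eggs) {
    eggs <- lapply(m, function(mi) {
      flags <- rep(FALSE, n_trivalents)
      if (mi > 0L) flags[sample.int(n_trivalents, mi)] <- TRUE
      apply_restitution(segregate(segregation_pattern(flags)))
    })
  }
  list(freq = counts / n_eggs, counts = counts, m = m, eggs = eggs,
       n_trivalents = n_trivalents, seed = seed)
}

egg_class_levels <- function() {
  c("soumiae_like", "gallica_like", "diploid_like", "male_35_like",
    "other_aneuploid")
}

# class of the restituted egg as a function of m alone (2<->1 segregation of
# a uniform triploid followed by whole-complement doubling): m = n -> all x4;
# m = n/2 -> half x4, half x2; m = 0 -> all x2; anything else aneuploid.
m_to_class <- function(m, n_trivalents) {
  cls <- rep("other_aneuploid", length(m))
  cls[m == n_trivalents] <- "soumiae_like"
  if (n_trivalents %% 2L == 0L) {
    cls[m == n_trivalents %/% 2L] <- "gallica_like"
  }
  cls[m == 0L] <- "diploid_like"
  cls
}

#' Exact egg-class distribution
#'
#' Aggregates the exact binomial distribution of m over the egg classes of
#' \code{\link{classify_egg}}, for comparison with Monte-Carlo output.
#'
#' @param n_trivalents number of trivalents.
#' @return named numeric vector over the egg classes, summing to 1.
#' @export
exact_class_distribution <- function(n_trivalents) {
  dm <- exact_m_distribution(n_trivalents)
  m <- as.integer(names(dm))
  cls <- m_to_class(m, as.integer(n_trivalents))
  out <- tapply(dm, factor(cls, levels = egg_class_levels()), sum,
                default = 0)
  stats::setNames(as.numeric(out), egg_class_levels())
}

#' Derive an androgenetic (X0) male karyotype
#'
#' Three routes by which the \emph{Clonopsis} androgen males may arise:
#' \describe{
#'   \item{x_loss}{accidental loss of one X chromosome from the source
#'     karyotype (cn = 54 gallica-like egg -> the cn = 53 androgen clone).}
#'   \item{scheme_A_mis_segregation}{incorrect X segregation at meiosis I of
#'     the intermediate triploid female: the 17 autosomal trivalents
#'     segregate concordantly (doubled complements to one pole) while the X
#'     trivalent delivers a single X, with no restitution, giving cn = 35.}
#'   \item{direct_hybrid}{direct species hybridization producing a diploid
#'     male: uniform x2 autosomes with a single X (cn = 35 at n = 18).}
#' }
#'
#' @param source a \code{\link{karyotype}}; for
#'   \code{scheme_A_mis_segregation} it must be triploid, for \code{x_loss}
#'   it must carry at least one X.
#' @param mode one of \code{"x_loss"}, \code{"scheme_A_mis_segregation"},
#'   \code{"direct_hybrid"}.
#' @return the male \code{\link{karyotype}}.
#' @examples
#' b_egg <- karyotype(rep(c(4L, 2L), each = 9))       # cn = 54
#' total_cn(derive_androgen(b_egg, "x_loss"))          # 53
#' total_cn(derive_androgen(karyotype(3), "scheme_A_mis_segregation")) # 35
#' @export
derive_androgen <- function(source,
                            mode = c("x_loss", "scheme_A_mis_segregation",
                                     "direct_hybrid")) {
  mode <- match.arg(mode)
  stopifnot(inherits(source, "karyotype"))
  gc <- source$group_copies
  xg <- source$x_group
  if (mode == "x_loss") {
    if (gc[xg] < 1L) stop("cannot remove an X from an X-free karyotype")
    gc[xg] <- gc[xg] - 1L
    return(karyotype(gc, n_groups = source$n_groups, x_group = xg))
  }
  if (mode == "scheme_A_mis_segregation") {
    if (!all(gc == 3L)) {
      stop("scheme_A_mis_segregation requires a triploid source")
    }
    out <- rep(2L, source$n_groups)
    out[xg] <- 1L
    return(karyotype(out, n_groups = source$n_groups, x_group = xg))
  }
  # direct_hybrid: diploid male, X0
  out <- rep(2L, source$n_groups)
  out[xg] <- 1L
  karyotype(out, n_groups = source$n_groups, x_group = xg)
}

#' Tabulate the meiosis model: exact distribution plus simulated frequencies
#'
#' Convenience report combining \code{\link{exact_m_distribution}} and
#' \code{\link{simulate_eggs}} in one table, one row per m.
#'
#' @param n_trivalents number of trivalents.
#' @param n_eggs Monte-Carlo sample size (0 skips simulation).
#' @param seed integer seed.
#' @return data.frame with columns m, cn (of the restituted egg), class,
#'   exact_prob and sim_freq.
#' @export
meiosis_report <- function(n_trivalents = 18L, n_eggs = 1e5L, seed = 1L) {
  dm <- exact_m_distribution(n_trivalents)
  m <- as.integer(names(dm))
  out <- data.frame(
    m = m,
    cn = 2L * (as.integer(n_trivalents) + m),
    class = m_to_class(m, as.integer(n_trivalents)),
    exact_prob = as.numeric(dm),
    sim_freq = NA_real_
  )
  if (n_eggs > 0) {
    sim <- simulate_eggs(n_trivalents, n_eggs, seed)
    tab <- tabulate(sim$m + 1L, nbins = n_trivalents + 1L) / n_eggs
    out$sim_freq <- tab
  }
  out
}
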