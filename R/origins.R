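#' Individuals and gametes for origin scenarios
#'
#' An individual carries a karyotype, a multiset of parental-genome labels
#' (one per haploid set), a mitochondrial lineage label (always inherited
#' from the egg-providing mother, even under androgenesis) and a sex.
#'
#' @param karyotype a \code{\link{karyotype}}.
#' @param nuclear_origin character vector of parental-genome labels, one per
#'   haploid set; its length must equal the modal per-group copy count.
#' @param mtdna_label mitochondrial lineage label.
#' @param sex \code{"female"} or \code{"male"}.
#' @return object of class \code{individual}.
#' @export
individual <- function(karyotype, nuclear_origin, mtdna_label,
                       sex = c("female", "male")) {
  sex <- match.arg(sex)
  stopifnot(inherits(karyotype, "karyotype"))
  nuclear_origin <- as.character(nuclear_origin)
  modal <- modal_copies(karyotype)
  if (length(nuclear_origin) != modal) {
    stop("nuclear_origin must carry one label per haploid set (",
         modal, " expected, ", length(nuclear_origin), " given)")
  }
  structure(list(karyotype = karyotype, nuclear_origin = nuclear_origin,
                 mtdna_label = as.character(mtdna_label), sex = sex),
            class = "individual")
}

modal_copies <- function(k) {
  tab <- table(k$group_copies)
  as.integer(names(tab)[which.max(tab)])
}

#' @export
print.individual <- function(x, ...) {
  cat("Individual (", x$sex, "): cn =", total_cn(x$karyotype),
      "| nuclear =", paste(x$nuclear_origin, collapse = "+"),
      "| mtDNA =", x$mtdna_label, "\n")
  invisible(x)
}

#' Construct a gamete
#'
#' @param karyotype a \code{\link{karyotype}}; haploid gametes are uniform
#'   x1, diploid (unreduced) gametes uniform x2.
#' @param origin \code{"egg"} or \code{"sperm"}.
#' @param parent_labels parental-genome labels carried (one per haploid set).
#' @param mtdna_label for eggs, the mother's mitochondrial label.
#' @return object of class \code{gamete} with a \code{ploidy} field.
#' @export
gamete <- function(karyotype, origin = c("egg", "sperm"), parent_labels,
                   mtdna_label = NA_character_) {
  origin <- match.arg(origin)
  stopifnot(inherits(karyotype, "karyotype"))
  pl <- ploidy_class(karyotype)
  if (!pl %in% c("haploid", "diploid")) {
    stop("gametes must be uniformly haploid or diploid, got ", pl)
  }
  parent_labels <- as.character(parent_labels)
  need <- if (pl == "haploid") 1L else 2L
  if (length(parent_labels) != need) {
    stop("a ", pl, " gamete carries ", need, " haploid-set label(s)")
  }
  structure(list(karyotype = karyotype, ploidy = pl, origin = origin,
                 parent_labels = parent_labels, mtdna_label = mtdna_label),
            class = "gamete")
}

#' Make a diploid hybrid individual
#'
#' The first step toward the \emph{Clonopsis} parthenogens: a diploid
#' hybrid carrying two complete chromosome series from two (possibly
#' identical, for race-level or control crosses) parental genomes.
#'
#' @param p1_label,p2_label parental-genome labels.
#' @param n_groups haploid group count (default 18).
#' @param mtdna_label mitochondrial label (defaults to \code{p1_label},
#'   treating parent 1 as the egg mother).
#' @param sex sex of the hybrid.
#' @return an \code{\link{individual}} with a uniform x2 karyotype,
#'   cn = 2 * n_groups.
#' @export
make_diploid_hybrid <- function(p1_label, p2_label, n_groups = 18L,
                                mtdna_label = p1_label, sex = "female") {
  k <- karyotype(2L, n_groups = n_groups,
                 origin_labels = c(p1_label, p2_label))
  individual(k, nuclear_origin = c(p1_label, p2_label),
             mtdna_label = mtdna_label, sex = sex)
}

#' Produce a gamete from a diploid parent
#'
#' Normal meiosis yields a haploid gamete with one full chromosome series.
#' Pre-meiotic, intra-meiotic and post-meiotic restitution differ in their
#' cytology but invariably produce the same outcome: an unreduced diploid
#' gamete carrying the parent's full complement.
#'
#' @param parent a diploid \code{\link{individual}}.
#' @param mechanism one of \code{"normal_haploid"}, \code{"premeiotic"},
#'   \code{"intrameiotic"}, \code{"postmeiotic"}.
#' @param set for \code{normal_haploid}, which haploid set (1 or 2) the
#'   gamete carries; defaults to 1. Recombination is not modelled, so a
#'   haploid gamete carries one intact parental series.
#' @return a \code{\link{gamete}} (egg for female parents, sperm for males).
#' @export
make_gamete <- function(parent,
                        mechanism = c("normal_haploid", "premeiotic",
                                      "intrameiotic", "postmeiotic"),
                        set = 1L) {
  mechanism <- match.arg(mechanism)
  stopifnot(inherits(parent, "individual"))
  if (ploidy_class(parent$karyotype) != "diploid") {
    stop("make_gamete requires a diploid parent")
  }
  ng <- parent$karyotype$n_groups
  origin <- if (parent$sex == "female") "egg" else "sperm"
  mt <- if (origin == "egg") parent$mtdna_label else NA_character_
  if (mechanism == "normal_haploid") {
    gamete(karyotype(1L, n_groups = ng), origin = origin,
           parent_labels = parent$nuclear_origin[[set]], mtdna_label = mt)
  } else {
    gamete(karyotype(2L, n_groups = ng), origin = origin,
           parent_labels = parent$nuclear_origin, mtdna_label = mt)
  }
}

#' Fuse gametes into a zygote: syngamy or androgenesis
#'
#' Syngamy combines the egg's and one sperm's chromosome sets. Under
#' androgenesis the egg pronucleus contributes nothing: the embryo's
#' nuclear genome comes from the sperm only, by doubling of a single sperm
#' head or fusion of several (stick insect eggs are polyspermic). In both
#' modes the mitochondrial label is the egg's: mtDNA is strictly maternal.
#'
#' @param egg an egg \code{\link{gamete}}.
#' @param sperm a single sperm gamete or a list of sperm gametes
#'   (androgenesis accepts several; one sperm implies doubling).
#' @param mode \code{"syngamy"} or \code{"androgenesis"}.
#' @param sex sex of the offspring (default female).
#' @param double_single_sperm under androgenesis with a single sperm, double
#'   the sperm head (default TRUE); set FALSE to take the sperm complement
#'   as-is, e.g. when a single unreduced diploid sperm already supplies a
#'   balanced genome.
#' @return an \code{\link{individual}}.
#' @examples
#' mom <- make_diploid_hybrid("A", "A", mtdna_label = "matA")
#' dad <- make_diploid_hybrid("B", "C", sex = "male")
#' tri <- fuse(make_gamete(mom), make_gamete(dad, "premeiotic"), "syngamy")
#' total_cn(tri$karyotype)  # 54
#' @export
fuse <- function(egg, sperm, mode = c("syngamy", "androgenesis"),
                 sex = "female", double_single_sperm = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(egg, "gamete"), egg$origin == "egg")
  if (inherits(sperm, "gamete")) sperm <- list(sperm)
  if (length(sperm) == 0L) stop("at least one sperm is required")
  ok <- vapply(sperm, function(s) inherits(s, "gamete") &&
                 s$origin == "sperm", logical(1))
  if (!all(ok)) stop("sperm must be sperm gametes")
  if (mode == "syngamy" && length(sperm) != 1L) {
    stop("syngamy requires exactly one sperm")
  }
  ng <- egg$karyotype$n_groups
  sperm_copies <- Reduce(`+`, lapply(sperm, function(s) s$karyotype$group_copies))
  sperm_labels <- unlist(lapply(sperm, `[[`, "parent_labels"))
  if (mode == "syngamy") {
    copies <- egg$karyotype$group_copies + sperm_copies
    labels <- c(egg$parent_labels, sperm_labels)
  } else if (length(sperm) == 1L && double_single_sperm) {
    # androgenesis with a single sperm: the sperm head doubles
    copies <- 2L * sperm_copies
    labels <- rep(sperm_labels, 2L)
  } else {
    copies <- sperm_copies
    labels <- sperm_labels
  }
  k <- karyotype(copies, n_groups = ng, origin_labels = labels)
  individual(k, nuclear_origin = labels, mtdna_label = egg$mtdna_label,
             sex = sex)
}

#' Construct the intermediate triploid female
#'
#' The hypothesized founder of the \emph{Clonopsis} polyploid parthenogens:
#' a female with three complete chromosome series (cn = 54 at n = 18),
#' assembled either by syngamy (haploid egg + unreduced diploid sperm) or
#' by androgenesis (the sperm-derived sets only, in an egg whose pronucleus
#' is excluded). The data cannot decide between the two routes, so both are
#' first-class and no default is asserted.
#'
#' @param mode \code{"syngamy"} or \code{"androgenesis"}.
#' @param labels character vector of exactly three haploid-set labels; under
#'   syngamy the first is the egg's set, the remaining two the sperm's.
#' @param mtdna_label the egg mother's mitochondrial label.
#' @param n_groups haploid group count (default 18).
#' @return a triploid female \code{\link{individual}}.
#' @export
make_triploid_female <- function(mode = c("syngamy", "androgenesis"),
                                 labels, mtdna_label, n_groups = 18L) {
  mode <- match.arg(mode)
  labels <- as.character(labels)
  if (length(labels) != 3L) stop("exactly three haploid-set labels required")
  k <- karyotype(3L, n_groups = n_groups, origin_labels = labels)
  individual(k, nuclear_origin = labels, mtdna_label = mtdna_label,
             sex = "female")
}
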