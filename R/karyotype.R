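#' Construct a karyotype
#'
#' A karyotype records, for each of the \code{n_groups} homologous chromosome
#' groups of the \emph{Clonopsis} complex (haploid number n = 18), how many
#' copies the cell carries. The X chromosome is one designated group among
#' the \code{n_groups} (by default the last), so an X0 male simply holds one
#' fewer copy at that group.
#'
#' @param group_copies integer vector of per-group copy counts, length
#'   \code{n_groups}; a single value is recycled.
#' @param n_groups haploid group count (default 18, the \emph{Clonopsis}
#'   haploid number).
#' @param x_group index of the X-bearing group (default \code{n_groups}).
#' @param origin_labels optional character vector of parental-genome labels,
#'   one per haploid set (e.g. \code{c("P1", "P2", "P2")} for a hybrid
#'   triploid). Purely numerical simulations may omit it.
#' @return an object of class \code{karyotype}.
#' @examples
#' total_cn(karyotype(3))            # triploid, cn = 54
#' ploidy_class(karyotype(2))        # "diploid"
#' @export
karyotype <- function(group_copies, n_groups = 18L, x_group = n_groups,
                      origin_labels = NULL) {
  n_groups <- as.integer(n_groups)
  if (n_groups < 1L) stop("n_groups must be >= 1")
  if (length(group_copies) == 1L) {
    group_copies <- rep(as.integer(group_copies), n_groups)
  }
  group_copies <- as.integer(group_copies)
  if (length(group_copies) != n_groups) {
    stop("group_copies must have length n_groups (", n_groups, ")")
  }
  if (any(is.na(group_copies)) || any(group_copies < 0L)) {
    stop("all copy counts must be non-negative integers")
  }
  x_group <- as.integer(x_group)
  if (x_group < 1L || x_group > n_groups) stop("x_group out of range")
  structure(
    list(group_copies = group_copies, n_groups = n_groups,
         x_group = x_group, origin_labels = origin_labels),
    class = "karyotype"
  )
}

#' @export
print.karyotype <- function(x, ...) {
  cat("Karyotype: cn =", total_cn(x), "(", x$n_groups, "groups, X = group",
      x$x_group, ",", sex_copies(x), "X copies )\n")
  cat("  class:", ploidy_class(x), "\n")
  tab <- table(x$group_copies)
  cat("  copies:", paste(sprintf("%s group(s) x%s", tab, names(tab)),
                         collapse = ", "), "\n")
  if (!is.null(x$origin_labels)) {
    cat("  origin:", paste(x$origin_labels, collapse = " + "), "\n")
  }
  invisible(x)
}

#' Total chromosome number of a karyotype
#'
#' @param k a \code{\link{karyotype}}.
#' @return integer cn, the sum of per-group copy counts.
#' @export
total_cn <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  sum(k$group_copies)
}

#' Copy count of the X-bearing group
#'
#' @param k a \code{\link{karyotype}}.
#' @return integer number of X chromosomes.
#' @export
sex_copies <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  k$group_copies[k$x_group]
}

#' Ploidy classification of a karyotype
#'
#' Uniform copy count c across all groups maps to the c-ploid label;
#' any non-uniform karyotype is aneuploid.
#'
#' @param k a \code{\link{karyotype}}.
#' @return one of \code{"haploid"}, \code{"diploid"}, \code{"triploid"},
#'   \code{"tetraploid"}, \code{"aneuploid"}.
#' @export
ploidy_class <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  cc <- unique(k$group_copies)
  if (length(cc) != 1L) return("aneuploid")
  switch(as.character(cc),
         "1" = "haploid", "2" = "diploid", "3" = "triploid",
         "4" = "tetraploid", "aneuploid")
}

#' Karyotype as a group/copies table
#'
#' @param x a \code{\link{karyotype}}.
#' @param ... unused.
#' @return data.frame with columns \code{group}, \code{copies}, \code{is_x}.
#' @export
as.data.frame.karyotype <- function(x, ...) {
  data.frame(group = seq_len(x$n_groups),
             copies = x$group_copies,
             is_x = seq_len(x$n_groups) == x$x_group)
}

#' Registry of Clonopsis species karyotypes
#'
#' The chromosome-number series of the North African \emph{Clonopsis}
#' complex: the bisexual species with XX/X0 sex determination (male
#' cn = female cn - 1), the all-female polyploid-series parthenogens built
#' on the haploid number n = 18 (36 = 2x18, 54 = 3x18, 72 = 4x18), and the
#' two clonal androgenetic male strains.
#'
#' @return data.frame with columns \code{name}, \code{female_cn},
#'   \code{male_cn} (NA where no male/female counterpart exists) and
#'   \code{reproductive_mode}.
#' @examples
#' species_registry()
#' @export
species_registry <- function() {
  reg <- data.frame(
    name = c("C. maroccana", "C. algerica", "C. felicitatis",
             "C. gallica", "C. soumiae",
             "C. androgenes-35", "C. androgenes-53"),
    female_cn = c(22L, 32L, 36L, 54L, 72L, NA_integer_, NA_integer_),
    male_cn = c(21L, 31L, 35L, NA_integer_, NA_integer_, 35L, 53L),
    reproductive_mode = c("bisexual", "bisexual", "bisexual",
                          "parthenogenetic", "parthenogenetic",
                          "androgenetic", "androgenetic"),
    stringsAsFactors = FALSE
  )
  class(reg) <- c("species_registry", "data.frame")
  reg
}

#' Serialize the species registry to JSON
#'
#' @param registry output of \code{\link{species_registry}}.
#' @param path optional file path; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
registry_json <- function(registry = species_registry(), path = NULL) {
  js <- jsonlite::toJSON(as.data.frame(registry), dataframe = "rows",
                         na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Write a karyotype as a CSV table
#'
#' @param k a \code{\link{karyotype}}.
#' @param path file path.
#' @export
write_karyotype_csv <- function(k, path) {
  utils::write.csv(as.data.frame(k), path, row.names = FALSE)
  invisible(path)
}
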