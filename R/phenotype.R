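#' The discrete adhesion-by-motility phenotype grid
#'
#' Cancer cells carry one of 144 phenotypes: every combination of cell-cell
#' adhesion and motility over the discrete values 0, 10, ..., 110 (energy and
#' force units of the Potts Hamiltonian, both bounded by twice the Metropolis
#' temperature).  Phenotype ids are stable: `id = 12 * adhesion/10 +
#' motility/10 + 1`.
#'
#' @return A data frame with one row per phenotype and columns
#'   `phenotype_id`, `adh_index`, `mot_index` (0-based grid indices) and
#'   `adhesion`, `motility` (parameter values).
#' @export
#' @examples
#' nrow(phenotype_grid())  # 144
phenotype_grid <- function() {
  g <- expand.grid(mot_index = 0:11, adh_index = 0:11)
  data.frame(
    phenotype_id = 12L * g$adh_index + g$mot_index + 1L,
    adh_index = g$adh_index,
    mot_index = g$mot_index,
    adhesion = 10 * g$adh_index,
    motility = 10 * g$mot_index
  )
}

#' Construct a phenotype from parameter values
#'
#' @param adhesion Cell-cell adhesion parameter; must be one of 0, 10, ..., 110.
#' @param motility Motility strength; must be one of 0, 10, ..., 110.
#' @return A named list of class `"phenotype"` with elements `adhesion`,
#'   `motility`, `adh_index`, `mot_index`, `phenotype_id`.
#' @export
phenotype <- function(adhesion, motility) {
  for (v in c(adhesion, motility)) {
    if (length(v) != 1 || is.na(v) || v %% 10 != 0 || v < 0 || v > 110) {
      stop("phenotype parameters must lie on the discrete grid 0, 10, ..., 110",
           call. = FALSE)
    }
  }
  i <- as.integer(adhesion / 10)
  j <- as.integer(motility / 10)
  structure(
    list(adhesion = adhesion, motility = motility,
         adh_index = i, mot_index = j,
         phenotype_id = 12L * i + j + 1L),
    class = "phenotype"
  )
}

#' @export
print.phenotype <- function(x, ...) {
  cat(sprintf("<phenotype %d: adhesion %g, motility %g>\n",
              x$phenotype_id, x$adhesion, x$motility))
  invisible(x)
}

#' Initial (seed) phenotype of the tumor
#'
#' The tumor seed starts in the middle of the parameter ranges.  The exact
#' center of the range 0..110 (55) is not a grid point, so the default sits
#' at (50, 50); both coordinates are configurable.
#'
#' @param adhesion,motility Seed parameter values on the grid.
#' @return A [phenotype()].
#' @export
initial_phenotype <- function(adhesion = 50, motility = 50) {
  phenotype(adhesion, motility)
}

#' Mutate a phenotype at cell division
#'
#' At each division there is a `probability` (default 4%) chance that one
#' uniformly chosen daughter changes one uniformly chosen parameter (adhesion
#' or motility) by one grid step (+10 or -10, uniform sign).  A step that
#' would leave the grid is, under the default `"abort"` boundary rule,
#' abandoned: both daughters keep the parent phenotype and the division
#' counts as unmutated.  Under `"reflect"` the step direction is inverted
#' instead.
#'
#' Uses R's RNG; seed with [set.seed()] for reproducibility.
#'
#' @param parent A [phenotype()].
#' @param probability Per-division mutation probability.
#' @param boundary Edge rule, `"abort"` (default) or `"reflect"`.
#' @return A list with elements `daughter1`, `daughter2` (phenotypes) and
#'   `mutated` (logical: did any parameter actually change).
#' @export
#' @examples
#' set.seed(1)
#' mutate_at_division(initial_phenotype())
mutate_at_division <- function(parent, probability = 0.04,
                               boundary = c("abort", "reflect")) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(parent, "phenotype"),
            probability >= 0, probability <= 1)
  d <- list(c(parent$adhesion, parent$motility),
            c(parent$adhesion, parent$motility))
  mutated <- FALSE
  if (runif(1) < probability) {
    which_d <- sample.int(2L, 1L)
    axis <- sample.int(2L, 1L)              # 1 adhesion, 2 motility
    step <- if (runif(1) < 0.5) -10 else 10
    val <- d[[which_d]][axis] + step
    if (val < 0 || val > 110) {
      if (boundary == "reflect") {
        val <- d[[which_d]][axis] - step
        d[[which_d]][axis] <- val
        mutated <- TRUE
      }
      # abort: leave both daughters unchanged
    } else {
      d[[which_d]][axis] <- val
      mutated <- TRUE
    }
  }
  list(daughter1 = phenotype(d[[1]][1], d[[1]][2]),
       daughter2 = phenotype(d[[2]][1], d[[2]][2]),
       mutated = mutated)
}

#' Write the phenotype table to a TSV file
#'
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phenotype_table <- function(path) {
  write.table(phenotype_grid(), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
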