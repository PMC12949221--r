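#' Scaled Gini-Simpson index of a two-pollinator community
#'
#' One minus the probability that two randomly drawn individuals are
#' conspecific, multiplied by 2 so that two equally abundant species score
#' 1: `2 * (1 - (R1^2 + R2^2) / (R1 + R2)^2)`. Equals 0 when only one
#' species is present.
#'
#' @param R1,R2 non-negative abundances (vectorised); their sum must be
#'   positive.
#' @return Values in \[0, 1\].
#' @examples
#' gini_simpson(1, 3)  # 0.75
#' @export
gini_simpson <- function(R1, R2) {
  check_abundance_pair(R1, R2)
  tot <- R1 + R2
  2 * (1 - (R1^2 + R2^2) / tot^2)
}

#' Rao's quadratic entropy of a two-pollinator community
#'
#' Abundance-weighted expected trait distance between two randomly drawn
#' individuals: `2 * R1 * R2 / (R1 + R2)^2 * |rho1 - rho2|`. Zero when the
#' traits coincide or one species is absent; at most `|rho1 - rho2| / 2`,
#' attained at equal abundances. This is the model's measure of functional
#' (as opposed to species) diversity.
#'
#' @param R1,R2 non-negative abundances (vectorised); their sum must be
#'   positive.
#' @param rho1,rho2 trait values of the two pollinators.
#' @return Non-negative values.
#' @examples
#' rao_q(1, 1, 1, 3)  # 1
#' @export
rao_q <- function(R1, R2, rho1, rho2) {
  check_abundance_pair(R1, R2)
  2 * R1 * R2 / (R1 + R2)^2 * abs(rho1 - rho2)
}

## zero out abundances below the extinction threshold before computing
## terminal-state diversity, so functional-diversity loss and species loss
## are counted with the same extinction semantics as the evolution loop.
threshold_extinct <- function(R, extinction_tol = 1e-3) {
  R[R < extinction_tol] <- 0
  R
}

check_abundance_pair <- function(R1, R2) {
  if (any(R1 < 0) || any(R2 < 0)) stop("abundances must be non-negative")
  if (any(R1 + R2 <= 0))
    stop("total abundance must be positive to compute a diversity index")
  invisible(NULL)
}
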