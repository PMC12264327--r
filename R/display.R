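#' Display characterization model
#'
#' The standard gain-gamma-offset model used to map device RGB to cone
#' excitations: per-channel gamma linearization followed by a 3x3 primary
#' matrix whose columns are the cone excitations of the full-drive primaries
#' (minus black level), plus a black-level offset,
#' `c = M %*% rgb^gamma + black`.
#'
#' @param gamma length-3 positive exponents, one per channel.
#' @param primary_matrix 3x3 matrix, rows L,M,S, columns R,G,B; must be
#'   invertible.
#' @param black_level `cone_excitations` emitted at RGB = (0,0,0); defaults
#'   to zero.
#' @return An object of class `display_model`.
#' @export
display_model <- function(gamma, primary_matrix,
                          black_level = structure(list(L = 0, M = 0, S = 0),
                                                  class = "cone_excitations")) {
  gamma <- as.numeric(gamma)
  stopifnot(length(gamma) == 3L, all(gamma > 0),
            is.matrix(primary_matrix), all(dim(primary_matrix) == c(3L, 3L)),
            inherits(black_level, "cone_excitations"))
  if (abs(det(primary_matrix)) < 1e-12) {
    stop("primary matrix must be invertible", call. = FALSE)
  }
  structure(
    list(gamma = gamma, primary_matrix = primary_matrix,
         black_level = black_level),
    class = "display_model"
  )
}

#' Forward and inverse display transforms
#'
#' `display_forward()` maps device RGB in the unit cube to cone excitations;
#' `display_inverse()` is its exact algebraic inverse. Out-of-gamut targets
#' (a linearized channel outside `[0, 1]`) are clipped channelwise and the
#' result flagged via the `"out_of_gamut"` attribute.
#'
#' @param rgb numeric length 3 in `[0, 1]`.
#' @param model a `display_model`.
#' @return `display_forward()`: `cone_excitations`. `display_inverse()`: an
#'   RGB triplet with logical attribute `out_of_gamut`.
#' @export
display_forward <- function(rgb, model) {
  stopifnot(inherits(model, "display_model"))
  rgb <- as.numeric(rgb)
  if (length(rgb) != 3L || any(rgb < 0) || any(rgb > 1)) {
    stop("rgb must be three values in [0, 1]", call. = FALSE)
  }
  lin <- rgb^model$gamma
  v <- as.numeric(model$primary_matrix %*% lin)
  structure(
    list(L = v[1] + model$black_level$L,
         M = v[2] + model$black_level$M,
         S = v[3] + model$black_level$S),
    class = "cone_excitations"
  )
}

#' @rdname display_forward
#' @param target a `cone_excitations` object to reproduce.
#' @export
display_inverse <- function(target, model) {
  stopifnot(inherits(target, "cone_excitations"), inherits(model, "display_model"))
  v <- c(target$L - model$black_level$L,
         target$M - model$black_level$M,
         target$S - model$black_level$S)
  lin <- as.numeric(solve(model$primary_matrix, v))
  oog <- any(lin < -1e-9) || any(lin > 1 + 1e-9)
  lin <- pmin(pmax(lin, 0), 1)
  structure(lin^(1 / model$gamma), out_of_gamut = oog)
}
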