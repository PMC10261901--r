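#' Right-hand side of the combined 29-state model
#'
#' Evaluates the time derivative of the full state vector at given light
#' conditions. The clock side follows compact transcription-translation
#' kinetics: Hill repression/activation products for transcription,
#' mass-action complex formation, first-order degradation, an acute dawn
#' activation term \code{q * f * L * P} on the light-responsive genes
#' (CL, P97, EL, RVE8) and intensity-scaled light- or dark-specific
#' degradation on the flagged species. The photosynthetic side couples
#' the four gene pairs to CL (activation for \emph{Lhcb1}, repression for
#' \emph{psbA}, \emph{RbcS1}, \emph{atpA}) with GI inhibition of
#' \emph{Lhcb1} in the extended variant.
#'
#' @param y numeric state vector of length 29 (see
#'   \code{\link{clock_states}}), all components >= 0, \code{P} in [0,1].
#' @param params a \code{clock_params} object.
#' @param L,D light/dark flags in {0,1} with \code{L + D = 1}.
#' @param f dimensionless intensity scale (see
#'   \code{\link{intensity_scale}}).
#' @param variant \code{"extended"} (GI inhibits \emph{Lhcb1}) or
#'   \code{"control"} (CL activation only).
#' @return named numeric vector of derivatives, 1/h.
#' @export
clock_rhs <- function(y, params, L, D, f = 1,
                      variant = c("extended", "control")) {
  variant <- match.arg(variant)
  stopifnot(inherits(params, "clock_params"))
  clock_only <- length(y) == 21
  if (clock_only) y <- c(y, numeric(8))  # clock side only
  if (length(y) != 29) stop("state vector must have length 21 or 29")
  if (any(!is.finite(y))) stop("state vector must be finite")
  if (any(y < 0)) stop("state vector must be componentwise >= 0")
  if (y[21] > 1) stop("P must lie in [0, 1]")
  if (any(!is.finite(as.numeric(params)))) stop("parameters must be finite")
  if (!(L %in% c(0, 1)) || !(D %in% c(0, 1)) || L + D != 1)
    stop("L and D must be complementary 0/1 flags")
  dy <- .clock_rhs_cpp(as.numeric(y), as.numeric(params), L, D, f,
                       variant = if (variant == "extended") 0L else 1L)
  dy <- stats::setNames(dy, clock_states())
  if (clock_only) dy[1:21] else dy
}

#' Light-sensitive protein kinetics
#'
#' \code{dP/dt = s_p * D * (1 - P) - d_p * f * L * P}: the protein
#' accumulates in darkness towards saturation at 1 and is degraded in
#' light at a rate scaled by light intensity.
#'
#' @param P active fraction in [0, 1].
#' @param L,D light/dark flags.
#' @param params a \code{clock_params} (uses \code{s_p}, \code{d_p}).
#' @param f intensity scale (default 1).
#' @return dP/dt (1/h).
#' @export
light_protein_rhs <- function(P, L, D, params, f = 1) {
  if (any(P < 0 | P > 1)) stop("P must lie in [0, 1]")
  unname(params[["s_p"]] * D * (1 - P) - params[["d_p"]] * f * L * P)
}

#' Lhcb1 transcription kinetics
#'
#' Extended variant: \code{dM/dt = v7 * CL^h/(K17^h + CL^h) *
#' K18^h/(K18^h + GI^h) - k7 * M}. Control variant omits the GI factor.
#'
#' @param M Lhcb1 mRNA level.
#' @param CL,GI clock protein levels.
#' @param params a \code{clock_params} or named vector with \code{v7},
#'   \code{k7}, \code{K17}, \code{K18}, \code{hill}.
#' @param variant \code{"extended"} or \code{"control"}.
#' @return dM/dt.
#' @export
lhcb1_rhs <- function(M, CL, GI, params, variant = c("extended", "control")) {
  variant <- match.arg(variant)
  if (any(c(M, CL, GI) < 0)) stop("inputs must be >= 0")
  h <- params[["hill"]]
  act <- CL^h / (params[["K17"]]^h + CL^h)
  if (variant == "extended")
    act <- act * params[["K18"]]^h / (params[["K18"]]^h + GI^h)
  params[["v7"]] * act - params[["k7"]] * M
}

#' CL-repressed photosynthetic gene transcription
#'
#' \code{dM/dt = v * K^h/(K^h + CL^h) - k * M}, the form shared by
#' \emph{psbA}, \emph{RbcS1} and \emph{atpA}.
#'
#' @param M mRNA level.
#' @param CL clock protein level.
#' @param v,K,k maximal rate, repression threshold, degradation rate.
#' @param hill Hill exponent (default 2).
#' @return dM/dt.
#' @export
repressed_gene_rhs <- function(M, CL, v, K, k, hill = 2) {
  if (any(c(M, CL) < 0)) stop("inputs must be >= 0")
  v * K^hill / (K^hill + CL^hill) - k * M
}

#' Linear translation/degradation kinetics
#'
#' \code{dProt/dt = p_trans * M - d_prot * Prot}.
#'
#' @param M mRNA level.
#' @param Prot protein level.
#' @param p_trans,d_prot translation and degradation rates (1/h).
#' @return dProt/dt.
#' @export
protein_rhs <- function(M, Prot, p_trans, d_prot) {
  if (any(c(M, Prot) < 0)) stop("inputs must be >= 0")
  p_trans * M - d_prot * Prot
}

#' Photosynthetic gas-exchange coefficients
#'
#' Coefficient container for the Hill output model of one gas-exchange
#' parameter: \code{P_i = alpha + (CL^2/(K1^2+CL^2) +
#' sum_j X_j^2/(H_j^2+X_j^2)) * K3^2/(K2^2+GI^2)}, where the \code{X_j}
#' are the protein levels of Lhcb1, psbA, RbcS1 and atpA.
#'
#' @param alpha basal rate in the parameter's native units.
#' @param K1 CL activation threshold (rel. units).
#' @param K2 GI inhibition threshold (rel. units).
#' @param K3 output amplitude scale (same units as \code{alpha} to the
#'   power 1/2 times \code{K2}; effectively an amplitude knob).
#' @param H length-4 numeric, promotion thresholds for Lhcb1, psbA,
#'   RbcS1, atpA proteins.
#' @return object of class \code{photo_coef}.
#' @export
photo_coef <- function(alpha, K1, K2, K3, H) {
  H <- as.numeric(H)
  if (length(H) != 4) stop("H must have length 4")
  vals <- c(alpha = alpha, K1 = K1, K2 = K2, K3 = K3,
            H_Lhcb1 = H[1], H_psbA = H[2], H_RbcS1 = H[3], H_atpA = H[4])
  if (any(vals <= 0)) stop("all coefficients must be > 0")
  structure(as.list(vals), class = "photo_coef")
}

#' @export
print.photo_coef <- function(x, ...) {
  cat("<photo_coef>", paste(sprintf("%s=%.4g", names(x), unlist(x)),
                            collapse = " "), "\n")
  invisible(x)
}

#' Photosynthetic parameter output model
#'
#' Evaluates the Hill output model (see \code{\link{photo_coef}}) for one
#' of \code{Pn}, \code{Gs}, \code{Ci}, \code{Tr}. The output is bounded
#' below by \code{alpha} (at zero drivers) and above by
#' \code{alpha + 5 * K3^2 / K2^2}, is increasing in CL and each protein
#' driver and decreasing in GI.
#'
#' @param CL,GI clock protein abundances (rel. units), scalars or vectors
#'   of a common length.
#' @param X matrix (n x 4) or length-4 vector of Lhcb1, psbA, RbcS1, atpA
#'   protein levels.
#' @param coef a \code{photo_coef}.
#' @return numeric vector of parameter values.
#' @export
photosynthetic_parameter <- function(CL, GI, X, coef) {
  stopifnot(inherits(coef, "photo_coef"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != 4) stop("X must have 4 columns")
  if (any(CL < 0) || any(GI < 0) || any(X < 0))
    stop("all drivers must be >= 0")
  H <- unlist(coef[c("H_Lhcb1", "H_psbA", "H_RbcS1", "H_atpA")])
  hillsum <- CL^2 / (coef$K1^2 + CL^2)
  for (j in 1:4) hillsum <- hillsum + X[, j]^2 / (H[j]^2 + X[, j]^2)
  unname(coef$alpha + hillsum * coef$K3^2 / (coef$K2^2 + GI^2))
}
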