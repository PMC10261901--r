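#' State variables of the combined model
#'
#' Returns the canonical names and ordering of the 29 state variables:
#' 21 clock-side states (6 mRNAs, 6 proteins, 8 active-protein/complex
#' pools, and the light-sensitive protein \code{P}) followed by the 8
#' photosynthetic-side states (mRNA/protein pairs for \emph{Lhcb1},
#' \emph{psbA}, \emph{RbcS1}, \emph{atpA}).
#'
#' @param side one of \code{"all"}, \code{"clock"}, \code{"photo"},
#'   \code{"mrna"} (the six clock mRNAs).
#' @return character vector of state names in integration order.
#' @export
clock_states <- function(side = c("all", "clock", "photo", "mrna")) {
  side <- match.arg(side)
  clock <- c("MCL", "CL", "MP97", "P97", "MP51", "P51",
             "MEL", "EL", "MGI", "GI", "MRVE8", "RVE8",
             "EC", "RL", "ZG", "ZTL", "COP1c", "COP1n", "COP1d", "HY5",
             "P")
  photo <- c("MLhcb1", "Lhcb1", "MpsbA", "psbA",
             "MRbcS1", "RbcS1", "MatpA", "atpA")
  switch(side,
         all   = c(clock, photo),
         clock = clock,
         photo = photo,
         mrna  = c("MCL", "MP97", "MP51", "MEL", "MGI", "MRVE8"))
}

#' Clock mRNA name for a gene label and vice versa
#' @keywords internal
.gene_mrna <- c(CL = "MCL", P97 = "MP97", P51 = "MP51",
                EL = "MEL", GI = "MGI", RVE8 = "MRVE8",
                Lhcb1 = "MLhcb1", psbA = "MpsbA",
                RbcS1 = "MRbcS1", atpA = "MatpA")

#' Parameter registry
#'
#' The single source of truth for the model's 100 named parameters: name,
#' unit, default bounds, and whether the parameter is free in fits. The
#' ordering is the ordering the integrator expects. The two
#' post-translational couplings (COP1 action on the evening complex,
#' \code{g_ec}, and ZTL/ZG-mediated dark destabilisation of P51,
#' \code{d3z}) default to fixed at zero: fits found them quantitatively
#' dispensable, so the default is the lower-dimensional parameter set.
#' Structural constants (Hill exponent, light-function constants) are also
#' fixed.
#'
#' @return data.frame with columns \code{name}, \code{unit}, \code{lower},
#'   \code{upper}, \code{free}.
#' @export
param_registry <- function() {
  reg <- function(names, unit, lower, upper, free = TRUE)
    data.frame(name = names, unit = unit, lower = lower, upper = upper,
               free = free, stringsAsFactors = FALSE)

  tab <- rbind(
    # CL (CCA1/LHY) mRNA + protein
    reg(c("v1", "q1"), c("units/h"), c(0.05, 0), c(50, 20)),
    reg(c("K1", "K2", "K3"), "units", 0.01, 5),
    reg("a1", "1", 0, 5), reg("K4", "units", 0.01, 5),
    reg(c("m1", "m1d"), "1/h", c(0.05, 0), c(8, 3)),
    reg("p1", "1/h", 0.05, 10), reg("d1", "1/h", 0.05, 8),
    # P97 (PRR9/PRR7)
    reg(c("v2", "q2"), "units/h", c(0.05, 0), c(50, 20)),
    reg(c("K5", "K6"), "units", 0.01, 5),
    reg("m2", "1/h", 0.05, 8),
    reg("p2", "1/h", 0.05, 10), reg("d2", "1/h", 0.05, 8),
    # P51 (PRR5/TOC1)
    reg("v3", "units/h", 0.05, 50),
    reg(c("K7", "K15"), "units", 0.01, 5),
    reg("c3", "1", 0, 1), reg("K8", "units", 0.01, 5),
    reg("m3", "1/h", 0.05, 8),
    reg("p3", "1/h", 0.05, 10), reg("d3", "1/h", 0.05, 8),
    reg("d3z", "1/(units*h)", 0, 2, free = FALSE),
    # EL (ELF4/LUX)
    reg(c("v4", "q4"), "units/h", c(0.05, 0), c(50, 20)),
    reg("K9", "units", 0.01, 5), reg("c4", "1", 0, 1),
    reg("K10", "units", 0.01, 5),
    reg(c("m4", "m4l"), "1/h", c(0.05, 0), c(8, 3)),
    reg("p4", "1/h", 0.05, 10), reg("d4", "1/h", 0.05, 8),
    # GI
    reg("v5", "units/h", 0.05, 50),
    reg(c("K11", "K12", "K13"), "units", 0.01, 5),
    reg(c("m5", "m5l"), "1/h", c(0.05, 0), c(8, 3)),
    reg("p5", "1/h", 0.05, 10), reg("d5", "1/h", 0.05, 8),
    # RVE8
    reg(c("v6", "q6"), "units/h", c(0.05, 0), c(50, 20)),
    reg("K14", "units", 0.01, 5), reg("m6", "1/h", 0.05, 8),
    reg("p6", "1/h", 0.05, 10), reg("d6", "1/h", 0.05, 8),
    reg("d6d", "1/h", 0, 2),
    # evening complex EC
    reg("c_ec", "units/h", 0.05, 10), reg("K_ec", "units", 0.01, 5),
    reg("d_ec", "1/h", 0.05, 5),
    reg("g_ec", "1/(units*h)", 0, 2, free = FALSE),
    # RVE8-LNK complex RL
    reg("c_rl", "1/h", 0.05, 5), reg("d_rl", "1/h", 0.05, 5),
    # ZTL-GI complex ZG and free ZTL
    reg("g_zg", "1/(units*h)", 0, 2), reg("q_zg", "1", 0, 5),
    reg(c("r_zg", "d_zg"), "1/h", 0.01, 5),
    reg("v_zt", "units/h", 0.01, 5), reg("d_zt", "1/h", 0.01, 5),
    # COP1 conversion chain
    reg("v_cc", "units/h", 0.01, 5), reg("d_cc", "1/h", 0.01, 5),
    reg("k_cn", "1/h", 0.01, 5),
    reg(c("k_nd", "k_dn"), "1/h", 0.01, 5),
    reg(c("d_cn", "d_cd"), "1/h", 0.01, 5),
    # HY5
    reg("v_hy", "units/h", 0.01, 5), reg("d_hy", "1/h", 0.01, 5),
    reg("g_hy", "1/(units*h)", 0, 5),
    # light-sensitive protein P
    reg("s_p", "1/h", 0.01, 5), reg("d_p", "1/h", 0.01, 5),
    # Lhcb1
    reg("v7", "units/h", 0.05, 20),
    reg(c("K17", "K18"), "units", 0.01, 5),
    reg("k7", "1/h", 0.05, 5), reg(c("p7", "d7"), "1/h", 0.05, 5),
    # psbA
    reg("v8", "units/h", 0.05, 20), reg("K19", "units", 0.01, 5),
    reg("k8", "1/h", 0.05, 5), reg(c("p8", "d8"), "1/h", 0.05, 5),
    # RbcS1
    reg("v9", "units/h", 0.05, 20), reg("K20", "units", 0.01, 5),
    reg("k9", "1/h", 0.05, 5), reg(c("p9", "d9"), "1/h", 0.05, 5),
    # atpA
    reg("v10", "units/h", 0.05, 20), reg("K21", "units", 0.01, 5),
    reg("k10", "1/h", 0.05, 5), reg(c("p10", "d10"), "1/h", 0.05, 5),
    # light-intensity function constants
    reg("I_A", "1/(umol m-2 s-1)", 0, 0.01, free = FALSE),
    reg("I_B", "1", 1e-4, 10, free = FALSE),
    reg("I_C", "umol m-2 s-1", 0, 500, free = FALSE),
    # shared Hill exponent
    reg("hill", "1", 1, 4, free = FALSE)
  )
  rownames(tab) <- NULL
  stopifnot(nrow(tab) == 100L, !anyDuplicated(tab$name))
  tab
}

#' Names of all model parameters, in integrator order
#' @export
param_names <- function() param_registry()$name
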