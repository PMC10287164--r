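## Two-pool steady-state kinetics and the limiting-PIC translation model.
##
## Each gene is transcribed at rate alpha into a capped pool C, which is
## decapped at rate delta into an uncapped pool U, itself degraded 5'->3' at
## rate gamma.  A small background turnover mu (> 0, keeps both pools finite)
## acts on both pools.  At steady state:
##
##   C = alpha / (delta + mu)
##   U = delta * C / (gamma + mu)
##
## A genotype modifies delta (per dependence class), gamma, and alpha
## (global buffering b times gene-specific induction).  The model is a
## minimal kinetic realization of the capped-fraction (C/T) diagnostic: a
## decapping-null genotype drives U to zero, so C/T rises to unity for every
## gene, whereas an exonuclease-null genotype accumulates the uncapped pool.

#' Genotype effect table
#'
#' Maps a genotype name to its multipliers on the kinetic model: a
#' dependence-class -> decapping multiplier map, a 5'->3' decay multiplier,
#' a global transcription buffering factor `b`, an induction factor applied
#' to transcriptionally induced (iESR-like) genes, and the factor on the
#' total PIC pool.  Wild type maps to all ones.
#'
#' Defaults encode: decapping-null genotypes (`dcp2`, `dcp2dhh1`) abolish
#' decapping for every class, buffer transcription globally by `1/1.3`, and
#' carry a reduced PIC pool (ribosome production falls with the repressed
#' ribosomal regulon); activator-null genotypes (`dhh1`, `pat1`, `edc3scd6`)
#' reduce decapping only for activator-dependent genes; `upf1` does the same
#' for NMD-dependent genes; `xrn1` abolishes uncapped-pool decay and is also
#' buffered.
#'
#' @param genotype one of `"WT"`, `"dcp2"`, `"dhh1"`, `"dcp2dhh1"`,
#'   `"xrn1"`, `"upf1"`, `"pat1"`, `"edc3scd6"`
#' @param config resolved configuration list (see [simConfig()]); only the
#'   `effects` block is consulted
#' @return list with elements `genotype`, `decappingMultiplier` (named
#'   vector over dependence classes), `gammaMultiplier`, `txnBuffering`,
#'   `txnInduction`, `picFactor`
#' @examples
#' genotypeEffect("WT")$decappingMultiplier
#' genotypeEffect("dcp2")$txnBuffering
#' @export
genotypeEffect <- function(genotype, config = simConfig()) {
    eff <- config$effects
    classes <- c("DHH1_DEP", "NMD_DEP", "BASAL")
    ones <- stats::setNames(rep(1, 3), classes)
    relief <- 1 / eff$activatorBoost
    out <- switch(genotype,
        WT = list(decapping = ones, gammaMult = 1, b = 1, induction = 1, pic = 1),
        dcp2 = ,
        dcp2dhh1 = list(decapping = ones * 0, gammaMult = 1,
                        b = eff$txnBuffering, induction = eff$txnInduction,
                        pic = eff$picFactor),
        dhh1 = ,
        pat1 = ,
        edc3scd6 = list(
            decapping = stats::setNames(c(relief, 1, 1), classes),
            gammaMult = 1, b = 1, induction = 1, pic = 1),
        upf1 = list(
            decapping = stats::setNames(c(1, relief, 1), classes),
            gammaMult = 1, b = 1, induction = 1, pic = 1),
        xrn1 = list(decapping = ones, gammaMult = 0,
                    b = eff$txnBuffering, induction = 1, pic = 1),
        stop("unknown genotype: ", genotype))
    if (any(unlist(out[c("decapping", "gammaMult", "b", "induction", "pic")]) < 0))
        stop("genotype effect multipliers must be >= 0")
    list(genotype = genotype,
         decappingMultiplier = out$decapping,
         gammaMultiplier = out$gammaMult,
         txnBuffering = out$b,
         txnInduction = out$induction,
         picFactor = out$pic)
}

#' Steady-state capped and uncapped mRNA pools
#'
#' Evaluates the closed-form steady state of the two-pool decay model for a
#' set of genes under a genotype effect.  With effective decapping rate
#' `d = delta0 * mult(dep_class)` and effective 5'->3' rate
#' `g = gamma * gammaMultiplier`:
#'
#' \deqn{C = \alpha \cdot ind \cdot b / (d + \mu), \qquad
#'       U = d\,C / (g + \mu), \qquad T = C + U.}
#'
#' Optionally a homeostatic transcription feedback couples the effective
#' transcription rate to the gene's own total pool: with reference totals
#' `refTotal` (wild type) and exponent `kappa`, the realized total solves
#' `T = A (refTotal/T)^kappa` where `A` is the feedback-free total, giving
#' `T = (A * refTotal^kappa)^(1/(1+kappa))` and a per-gene factor
#' `f = (refTotal/T)^kappa` on alpha.  `kappa = 0` (default) disables it and
#' reproduces the plain closed form.
#'
#' @param params data.frame-like with numeric columns `alpha`, `delta0`,
#'   `gamma`, `mu` and character `dep_class` (one of `DHH1_DEP`, `NMD_DEP`,
#'   `BASAL`); an optional logical `induced` column marks genes subject to
#'   the genotype's transcriptional induction
#' @param effect a genotype effect from [genotypeEffect()]
#' @param kappa homeostatic feedback exponent (>= 0)
#' @param refTotal per-gene reference totals for the feedback (required when
#'   `kappa > 0`)
#' @return data.frame with columns `C`, `U`, `T`, `cappedFraction`
#'   (`C/T`), and `alphaEff` (the realized transcription rate, the quantity
#'   Pol II occupancy reports on)
#' @examples
#' p <- data.frame(alpha = 10, delta0 = 0.4, gamma = 0.9, mu = 0.1,
#'                 dep_class = "BASAL")
#' steadyState(p, genotypeEffect("WT"))          # C = 20, U = 8
#' @export
steadyState <- function(params, effect, kappa = 0, refTotal = NULL) {
    alpha <- params$alpha; delta0 <- params$delta0
    gamma <- params$gamma; mu <- params$mu
    for (v in list(alpha, delta0, gamma, mu))
        if (any(!is.finite(v)) || any(v < 0))
            stop("kinetic parameters must be finite and >= 0")
    if (any(mu <= 0)) stop("mu must be > 0 (pools must be finite)")
    if (kappa < 0) stop("kappa must be >= 0")
    mult <- effect$decappingMultiplier[as.character(params$dep_class)]
    if (any(is.na(mult))) stop("unknown dependence class in params")
    ind <- rep(1, length(alpha))
    if (!is.null(params$induced)) ind[params$induced] <- effect$txnInduction
    d <- delta0 * mult
    g <- gamma * effect$gammaMultiplier
    if (any(g + mu <= 0)) stop("gamma + mu must be > 0")
    alphaBase <- alpha * ind * effect$txnBuffering
    ## feedback-free total is linear in alpha
    h <- (1 / (d + mu)) * (1 + d / (g + mu))
    A <- alphaBase * h
    if (kappa > 0) {
        if (is.null(refTotal))
            stop("refTotal is required when kappa > 0")
        Ttot <- (A * refTotal^kappa)^(1 / (1 + kappa))
        f <- ifelse(A > 0, (refTotal / Ttot)^kappa, 1)
    } else {
        Ttot <- A
        f <- rep(1, length(A))
    }
    alphaEff <- alphaBase * f
    C <- alphaEff / (d + mu)
    U <- d * C / (g + mu)
    data.frame(C = C, U = U, T = C + U,
               cappedFraction = ifelse(C + U > 0, C / (C + U), NA_real_),
               alphaEff = alphaEff)
}

#' Free-PIC level and per-mRNA occupancy under competition
#'
#' mRNAs compete for a limiting pool of 43S preinitiation complexes.  With
#' per-gene capped abundance `m_i`, initiation strength `s_i` and free-PIC
#' level `F`, the occupancy of each mRNA is `theta_i = s_i F / (1 + s_i F)`
#' and conservation of the pool requires
#'
#' \deqn{P_{total} = F + \sum_i m_i \frac{s_i F}{1 + s_i F}.}
#'
#' The left side minus the right is strictly monotone in `F`, so the root is
#' found by bisection on `[0, P_total]` to a residual below
#' `1e-9 * P_total`.  Per-gene translational output is proportional to
#' `theta_i * m_i * CDS length` and drives ribosome-footprint generation.
#'
#' @param m per-gene capped abundances (>= 0)
#' @param s per-gene initiation strengths (>= 0)
#' @param picTotal total PIC pool (> 0)
#' @return list with `F` (free PICs), `theta` (per-gene occupancy in
#'   `[0, 1]`) and `residual` (conservation residual at the solution)
#' @examples
#' solveFreePICs(1, 1, 2)$F   # sqrt(2): root of F + F/(1+F) = 2
#' @export
solveFreePICs <- function(m, s, picTotal) {
    if (!is.finite(picTotal) || picTotal <= 0)
        stop("picTotal must be > 0")
    if (length(m) != length(s)) stop("m and s must have equal length")
    if (any(m < 0) || any(s < 0)) stop("m and s must be >= 0")
    occupied <- function(F) sum(m * s * F / (1 + s * F))
    resid <- function(F) picTotal - F - occupied(F)
    tol <- 1e-9 * picTotal
    lo <- 0; hi <- picTotal     # resid(0) > 0 >= resid(picTotal)
    for (i in 1:200) {
        mid <- (lo + hi) / 2
        r <- resid(mid)
        if (abs(r) < tol) break
        if (r > 0) lo <- mid else hi <- mid
    }
    F <- mid
    list(F = F, theta = s * F / (1 + s * F), residual = resid(F))
}
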