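#' Specification of a synthetic twin cohort
#'
#' Defines a classical-twin-design cohort: monozygotic (MZ) pairs share all
#' additive genetic influences, dizygotic (DZ) pairs share half of them, and
#' both share common-environment influences. Per-trait variance is decomposed
#' into additive genetic (a2), common environment (c2) and unique environment
#' (e2) proportions which must sum to 1; the total variance of every trait is
#' 1, so `trait_means` sets location only. Cross-trait structure is given by
#' the genetic, common- and unique-environment correlation matrices.
#'
#' @param n_mz_pairs,n_dz_pairs number of MZ / DZ twin pairs.
#' @param traits character vector of trait names.
#' @param a2,c2,e2 per-trait variance proportions (recycled to
#'   `length(traits)`); each triple must sum to 1 within 1e-12.
#' @param rho_g,rho_c,rho_e cross-trait correlation matrices (default
#'   identity); must be symmetric positive semidefinite.
#' @param trait_means per-trait means (default 0).
#' @param sex_effect additive mean offset for males (females are reference);
#'   scalar or per-trait.
#' @param handedness_effect additive mean offset for non-right-handers;
#'   scalar or per-trait.
#' @param incomplete_fraction probability that a pair is incomplete (one
#'   co-twin's trait values missing), emulating longitudinal drop-out.
#' @param p_right probability of right-handedness per individual (default
#'   0.84, typical of a childhood cohort).
#' @param seed integer seed; generation is deterministic given the spec.
#' @return object of class `cohort_spec`.
#' @seealso [generate_twin_cohort()]
#' @export
cohort_spec <- function(n_mz_pairs, n_dz_pairs, traits = "trait",
                        a2 = 0.5, c2 = 0, e2 = NULL,
                        rho_g = NULL, rho_c = NULL, rho_e = NULL,
                        trait_means = 0, sex_effect = 0,
                        handedness_effect = 0, incomplete_fraction = 0,
                        p_right = 0.84, seed = 1L) {
  nt <- length(traits)
  a2 <- rep_len(a2, nt); c2 <- rep_len(c2, nt)
  if (is.null(e2)) e2 <- 1 - a2 - c2 else e2 <- rep_len(e2, nt)
  if (any(abs(a2 + c2 + e2 - 1) > 1e-12))
    stop("a2 + c2 + e2 must equal 1 for every trait (tolerance 1e-12)")
  if (any(c(a2, c2, e2) < -1e-12) || any(c(a2, c2, e2) > 1 + 1e-12))
    stop("variance proportions must lie in [0, 1]")
  stopifnot(n_mz_pairs >= 0, n_dz_pairs >= 0,
            incomplete_fraction >= 0, incomplete_fraction <= 1,
            p_right >= 0, p_right <= 1)
  fix_rho <- function(r, label) {
    if (is.null(r)) r <- diag(nt)
    r <- as.matrix(r)
    if (!all(dim(r) == nt)) stop(label, " must be ", nt, "x", nt)
    if (!is_psd(r)) stop(label, " must be symmetric positive semidefinite")
    if (any(abs(diag(r) - 1) > 1e-10)) stop(label, " must have unit diagonal")
    r
  }
  structure(list(
    n_mz_pairs = as.integer(n_mz_pairs), n_dz_pairs = as.integer(n_dz_pairs),
    traits = traits, a2 = a2, c2 = c2, e2 = e2,
    rho_g = fix_rho(rho_g, "rho_g"), rho_c = fix_rho(rho_c, "rho_c"),
    rho_e = fix_rho(rho_e, "rho_e"),
    trait_means = rep_len(trait_means, nt),
    sex_effect = rep_len(sex_effect, nt),
    handedness_effect = rep_len(handedness_effect, nt),
    incomplete_fraction = incomplete_fraction, p_right = p_right,
    seed = as.integer(seed)), class = "cohort_spec")
}

# A/C/E trait x trait covariance matrices implied by a cohort_spec
spec_components <- function(spec) {
  mk <- function(p2, rho) {
    d <- sqrt(p2)
    m <- outer(d, d) * rho
    (m + t(m)) / 2
  }
  list(A = mk(spec$a2, spec$rho_g), C = mk(spec$c2, spec$rho_c),
       E = mk(spec$e2, spec$rho_e))
}

#' Generate a twin cohort from a specification
#'
#' Draws one multivariate-normal vector per family from the 2-twin x n-trait
#' covariance implied by the A/C/E decomposition (via its Cholesky factor):
#' within-pair trait covariance is `A + C` for MZ pairs and `0.5 A + C` for DZ
#' pairs. Sex is assigned per pair (co-twins share sex in this design);
#' handedness per individual with `P(right) = p_right`. Mean offsets for males
#' and non-right-handers are added after the random draw. A fraction of pairs
#' is made incomplete by blanking one co-twin's trait values (the row is
#' retained with missing traits).
#'
#' @param spec a [cohort_spec()].
#' @return `data.frame` with columns `family_id`, `twin_index` (1 or 2),
#'   `zygosity` (`"MZ"`/`"DZ"`), `sex` (`"M"`/`"F"`), `handedness`
#'   (`"R"`/`"L"`) and one column per trait.
#' @export
generate_twin_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  comp <- spec_components(spec)
  nt <- length(spec$traits)
  P <- comp$A + comp$C + comp$E
  sigma_pair <- function(k) {
    W <- k * comp$A + comp$C
    rbind(cbind(P, W), cbind(W, P))
  }
  # PSD factor via eigendecomposition so singular-but-valid models
  # (e.g. a2 = 1 MZ pairs, which are exactly rank-deficient) still generate
  psd_factor <- function(S, zyg) {
    e <- eigen(S, symmetric = TRUE)
    if (any(e$values < -1e-8 * max(abs(e$values), 1)))
      stop("implied ", zyg, " pair covariance is not positive semidefinite; ",
           "check a2/c2/e2 and the correlation matrices")
    t(e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(S)))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  draw_group <- function(n, zyg, k, id0) {
    if (n == 0) return(NULL)
    L <- psd_factor(sigma_pair(k), zyg)            # y = z %*% L, cov = t(L) L
    Z <- matrix(stats::rnorm(n * 2 * nt), n, 2 * nt)
    Y <- Z %*% L
    sex <- sample(c("M", "F"), n, replace = TRUE)
    hand <- matrix(ifelse(stats::runif(2 * n) < spec$p_right, "R", "L"), n, 2)
    singleton <- stats::runif(n) < spec$incomplete_fraction
    drop_twin <- sample.int(2, n, replace = TRUE)
    # long format: rows (pair1 twin1, pair1 twin2, pair2 twin1, ...)
    tr <- matrix(NA_real_, 2 * n, nt)
    odd <- seq(1L, 2L * n, by = 2L)
    tr[odd, ] <- Y[, seq_len(nt), drop = FALSE]
    tr[odd + 1L, ] <- Y[, nt + seq_len(nt), drop = FALSE]
    male <- rep(sex == "M", each = 2)
    left <- as.vector(t(hand)) == "L"
    tr <- tr + rep(1, 2 * n) %o% spec$trait_means +
      male %o% spec$sex_effect + left %o% spec$handedness_effect
    blank <- (which(singleton) - 1L) * 2L + drop_twin[singleton]
    tr[blank, ] <- NA_real_
    out <- data.frame(family_id = id0 + rep(seq_len(n), each = 2),
                      twin_index = rep(1:2, n), zygosity = zyg,
                      sex = rep(sex, each = 2),
                      handedness = as.vector(t(hand)),
                      stringsAsFactors = FALSE)
    cbind(out, as.data.frame(tr))
  }
  out <- rbind(draw_group(spec$n_mz_pairs, "MZ", 1, 0L),
               draw_group(spec$n_dz_pairs, "DZ", 0.5, spec$n_mz_pairs))
  names(out) <- c("family_id", "twin_index", "zygosity", "sex", "handedness",
                  spec$traits)
  rownames(out) <- NULL
  out
}

#' Read/write phenotype tables
#'
#' CSV dialect: header `family_id,twin_index,zygosity,sex,handedness,<trait>...`,
#' missing trait values as empty fields.
#'
#' @param data phenotype `data.frame` as from [generate_twin_cohort()].
#' @param path file path.
#' @export
write_phenotypes <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}
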