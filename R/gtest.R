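# The canonical (unoptimized) G-test of conditional independence: the 2N-scaled
# log-likelihood-ratio statistic in nats, the per-stratum zero-eliminating
# degrees-of-freedom rule, and the chi-squared p-value. Every backend reports
# results through this module's verdict logic, so all four agree by design.

#' Configuration for conditional-independence tests
#'
#' @param alpha Significance level in (0,1); the null (independence) is
#'   rejected when `p < alpha` (strict, so ties at `p == alpha` keep the null).
#' @param min_samples_factor Reliability rule: when positive, a test whose
#'   potential contingency table has more than `N / min_samples_factor` cells
#'   is not attempted and returns independent. The default 0 disables the rule
#'   so verdicts are driven by the G-test alone.
#' @param backend One of `"default"`, `"static-adtree"`, `"dynamic-adtree"`,
#'   `"dcmi"`.
#' @param llt Leaf-list threshold for the AD-tree backends, as a percentage of
#'   N in `[0, 100]`; 0 disables leaf-lists.
#' @param spouse_conditioning Conditioning set used by the spouse test:
#'   `"sepset_union_x"` (the default: the separating set recorded for the
#'   candidate plus the linking PC member, which opens the collider while
#'   keeping every other path blocked) or `"pc_only"` (condition on PC(T);
#'   simpler but unsound in corner structures — see the methods vignette).
#' @return An object of class `ci_test_config`.
#' @export
ci_test_config <- function(alpha = 0.05, min_samples_factor = 0,
                           backend = c("default", "static-adtree",
                                       "dynamic-adtree", "dcmi"),
                           llt = 0,
                           spouse_conditioning = c("sepset_union_x",
                                                   "pc_only")) {
  backend <- match.arg(backend)
  spouse_conditioning <- match.arg(spouse_conditioning)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)")
  if (min_samples_factor < 0) stop("min_samples_factor must be >= 0")
  if (llt < 0 || llt > 100) stop("llt must be a percentage in [0,100]")
  structure(list(alpha = alpha, min_samples_factor = min_samples_factor,
                 backend = backend, llt = llt,
                 spouse_conditioning = spouse_conditioning),
            class = "ci_test_config")
}

# Positions of x, y and z within a ctab's feature tuple; errors unless the
# table covers exactly {x,y} union z.
xyz_positions <- function(ct, x, y, z) {
  want <- sort(unique(c(x, y, z)))
  if (length(want) != length(c(x, y, z)) ||
      !identical(sort(as.integer(ct$features)), as.integer(want)))
    stop("contingency table must cover exactly {x,y} union z")
  list(px = match(x, ct$features), py = match(y, ct$features),
       pz = match(z, ct$features))
}

# z-stratum id, x-value id and y-value id for every non-zero cell.
cell_strata <- function(ct, pos) {
  nc <- length(ct$counts)
  zcode <- if (length(pos$pz))
    encode_cells(ct$keys[, pos$pz, drop = FALSE], ct$arities[pos$pz])
  else rep(1, nc)
  list(zcode = zcode,
       xv = ct$keys[, pos$px], yv = ct$keys[, pos$py])
}

#' G statistic from a joint contingency table
#'
#' Computes `G(X,Y|Z) = 2N * sum P(x,y,z) ln[ P(x,y,z) P(z) / (P(x,z) P(y,z)) ]`
#' over the non-zero cells of the joint table — the joint-probability rewriting
#' of the conditional form `2N * sum P(x,y,z) ln[ P(x,y|z) / (P(x|z) P(y|z)) ]`.
#' Natural logarithm throughout; zero cells contribute nothing.
#'
#' @param joint A [contingency_table()] over exactly `{x, y}` union `z`.
#' @param x,y Feature indices (1-based), distinct, not in `z`.
#' @param z Integer vector of conditioning feature indices (may be empty).
#' @param n Total sample count; must equal `joint$total`.
#' @return The G statistic (non-negative up to float slack).
#' @export
g_statistic_from_counts <- function(joint, x, y, z = integer(0), n = joint$total) {
  if (n != joint$total) stop("n must equal the table total")
  pos <- xyz_positions(joint, x, y, z)
  st <- cell_strata(joint, pos)
  cnt <- as.numeric(joint$counts)
  # marginal counts by aggregation over the stored (non-zero) cells
  gsum <- function(code) {
    agg <- rowsum(cnt, group = code)
    agg[match(code, as.numeric(rownames(agg))), 1L]
  }
  ar_x <- joint$arities[pos$px]
  code_xz <- st$xv + ar_x * (st$zcode - 1)
  ar_y <- joint$arities[pos$py]
  code_yz <- st$yv + ar_y * (st$zcode - 1)
  n_xz <- gsum(code_xz)
  n_yz <- gsum(code_yz)
  n_z <- gsum(st$zcode)
  g <- 2 * sum(cnt * log(cnt * n_z / (n_xz * n_yz)))
  # exact independence can land at tiny negatives through cancellation
  if (g < 0 && g > -1e-9) g <- 0
  g
}

#' Degrees of freedom of a conditional G-test
#'
#' Per-stratum zero-eliminating rule: for each conditioning configuration `c`
#' observed in the data, count the x-values and y-values with positive count
#' inside that stratum and add `max(r_x(c)-1, 0) * max(r_y(c)-1, 0)`. With an
#' empty conditioning set the sum has a single global stratum. Value
#' combinations never observed contribute no degrees of freedom, which is what
#' makes the rule depend on the zeros of the joint probability mass function.
#'
#' @inheritParams g_statistic_from_counts
#' @return A non-negative integer (0 signals a degenerate test; see
#'   [ci_test_from_counts()]).
#' @export
degrees_of_freedom <- function(joint, x, y, z = integer(0)) {
  pos <- xyz_positions(joint, x, y, z)
  st <- cell_strata(joint, pos)
  strata <- unique(st$zcode)
  ar_x <- joint$arities[pos$px]
  ar_y <- joint$arities[pos$py]
  # distinct (x, stratum) pairs, counted per stratum
  rx <- table(st$zcode[!duplicated(st$xv + ar_x * (st$zcode - 1))])
  ry <- table(st$zcode[!duplicated(st$yv + ar_y * (st$zcode - 1))])
  key <- as.character(strata)
  rxv <- as.integer(rx[key]); rxv[is.na(rxv)] <- 0L
  ryv <- as.integer(ry[key]); ryv[is.na(ryv)] <- 0L
  sum(pmax(rxv - 1L, 0L) * pmax(ryv - 1L, 0L))
}

#' Upper-tail chi-squared p-value of a G statistic
#'
#' @param g Observed G statistic (>= 0).
#' @param dof Degrees of freedom (>= 1).
#' @return `P(chi2_dof >= g)`.
#' @export
g_p_value <- function(g, dof) {
  stopifnot(g >= -1e-9, dof >= 1)
  stats::pchisq(max(g, 0), df = dof, lower.tail = FALSE)
}

# Assemble a GTestResult from a computed (g, dof) pair. `n_potential_cells`
# is the full cardinality prod(arities of {x,y} union z), used only by the
# reliability rule.
finalize_gtest <- function(g, dof, x, y, z, n, n_potential_cells, cfg) {
  if (cfg$min_samples_factor > 0 &&
      n < cfg$min_samples_factor * n_potential_cells) {
    return(gtest_result(0, 0L, 1, TRUE, x, y, z))
  }
  if (dof == 0L) {
    # a constant feature (or fully degenerate stratification) carries no
    # information: accept independence rather than divide by a chi2(0)
    return(gtest_result(g, 0L, 1, TRUE, x, y, z))
  }
  p <- g_p_value(g, dof)
  gtest_result(g, dof, p, p >= cfg$alpha, x, y, z)
}

gtest_result <- function(g, dof, p, independent, x, y, z) {
  structure(list(g = g, dof = as.integer(dof), p_value = p,
                 independent = independent, x = as.integer(x),
                 y = as.integer(y), z = sort(as.integer(z))),
            class = "gtest_result")
}

#' @export
print.gtest_result <- function(x, ...) {
  ztxt <- if (length(x$z)) paste(x$z, collapse = ",") else "{}"
  cat(sprintf("G-test X%d vs X%d | {%s}: G = %.6g, dof = %d, p = %.4g -> %s\n",
              x$x, x$y, ztxt, x$g, x$dof, x$p_value,
              if (x$independent) "independent" else "dependent"))
  invisible(x)
}

#' @export
as.data.frame.gtest_result <- function(x, ...) {
  data.frame(x = x$x, y = x$y, z = paste(x$z, collapse = ","),
             g = x$g, dof = x$dof, p_value = x$p_value,
             independent = x$independent)
}

#' Canonical conditional-independence G-test from a joint table
#'
#' The unoptimized reference path: statistic, degrees of freedom, p-value and
#' verdict assembled from one joint contingency table.
#'
#' @inheritParams g_statistic_from_counts
#' @param cfg A [ci_test_config()].
#' @return A `gtest_result` with fields `g`, `dof`, `p_value`, `independent`,
#'   `x`, `y`, `z`.
#' @export
ci_test_from_counts <- function(joint, x, y, z = integer(0),
                                cfg = ci_test_config()) {
  g <- g_statistic_from_counts(joint, x, y, z)
  dof <- degrees_of_freedom(joint, x, y, z)
  finalize_gtest(g, dof, x, y, z, joint$total, prod(joint$arities), cfg)
}
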