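# Five-layer Takagi-Sugeno fuzzy network: sigmoidal memberships, eight rules
# (product t-norm), normalized firing strengths, first-order consequents.
# One network drives one of the six tunable plan parameters; the same forward
# pass serves the static controller (fixed parameters) and the trained one.

INPUTS <- c("ptv", "nt", "oar") # consequent coefficient order: 1, ptv, nt, oar
LABELS <- c("low", "high")
TPP_TARGETS <- c("pd_ptv", "pd_oar", "pd_nt", "wf_ptv", "wf_oar", "wf_nt")

#' Complete two-label rule table
#'
#' The eight antecedent combinations over \{low, high\} for the three relative
#' dose deviations. The published rule listing assigns the normal-tissue label
#' "high" to two rules with otherwise identical antecedents and omits the
#' (target high, OAR low, NT low) combination; a network with eight distinct
#' rules requires the full 2^3 truth table, so that combination replaces the
#' duplicate (rule 6). See the methods vignette.
#'
#' @return An 8 x 3 character matrix, columns `ptv`, `nt`, `oar`.
#' @export
rule_table_default <- function() {
  rt <- rbind(
    c("low",  "low",  "low"),  # R1
    c("low",  "high", "low"),  # R2
    c("low",  "low",  "high"), # R3
    c("low",  "high", "high"), # R4
    c("high", "high", "low"),  # R5
    c("high", "low",  "low"),  # R6 (repaired: completes the truth table)
    c("high", "low",  "high"), # R7
    c("high", "high", "high")  # R8
  )
  colnames(rt) <- INPUTS
  rownames(rt) <- paste0("R", 1:8)
  rt
}

#' Construct a fuzzy network parameter set
#'
#' @param premise List with numeric 3 x 2 matrices `a` (sigmoid slopes) and
#'   `b` (sigmoid centers); rows named `ptv`, `nt`, `oar`, columns `low`,
#'   `high` (12 premise parameters).
#' @param consequents 8 x 4 numeric matrix of first-order consequent
#'   coefficients; column j of row i multiplies (1, d_ptv, d_nt, d_oar).
#' @param rule_table 8 x 3 character matrix of antecedent labels; rows must be
#'   distinct and cover each input with `low`/`high`.
#' @param target Which plan parameter this network drives (one of `pd_ptv`,
#'   `pd_oar`, `pd_nt`, `wf_ptv`, `wf_oar`, `wf_nt`), or `NA`.
#' @return A `fuzzy_network` object.
#' @export
fuzzy_network <- function(premise, consequents,
                          rule_table = rule_table_default(),
                          target = NA_character_) {
  a <- matrix(as.numeric(premise$a), 3, 2,
              dimnames = list(INPUTS, LABELS))
  b <- matrix(as.numeric(premise$b), 3, 2,
              dimnames = list(INPUTS, LABELS))
  consequents <- matrix(as.numeric(consequents), 8, 4)
  if (length(a) != 6 || length(b) != 6) {
    abort("Premise must hold 12 parameters (3 inputs x 2 labels x {a, b}).")
  }
  if (nrow(rule_table) != 8 || ncol(rule_table) != 3 ||
      anyDuplicated(apply(rule_table, 1, paste, collapse = "|")) > 0) {
    abort("rule_table must list the 8 distinct antecedent combinations.")
  }
  structure(
    list(a = a, b = b, consequents = consequents,
         rule_table = rule_table,
         label_idx = matrix(match(rule_table, LABELS), 8, 3,
                            dimnames = dimnames(rule_table)),
         target = target),
    class = "fuzzy_network"
  )
}

#' @export
print.fuzzy_network <- function(x, ...) {
  cat("<fuzzy_network>", if (!is.na(x$target)) paste("driving", x$target),
      "- 12 premise + 32 consequent parameters\n")
  invisible(x)
}

#' Sigmoidal membership function
#'
#' `mu = 1 / (1 + exp(-a * (x - b)))`; saturates numerically at 0/1.
#'
#' @param x Relative dose deviation(s).
#' @param a Slope.
#' @param b Center.
#' @return Membership degree(s) in `[0, 1]`.
#' @export
membership <- function(x, a, b) {
  1 / (1 + exp(-a * (x - b)))
}

#' Rule firing strengths (product t-norm)
#'
#' @param mu 3 x 2 matrix of membership degrees (rows `ptv`, `nt`, `oar`;
#'   columns `low`, `high`).
#' @param rule_table 8 x 3 label matrix as in [rule_table_default()].
#' @return Length-8 vector of nonnegative firing strengths.
#' @export
fire_rules <- function(mu, rule_table = rule_table_default()) {
  li <- matrix(match(rule_table, LABELS), nrow(rule_table), 3)
  apply(li, 1, function(lab) mu[1, lab[1]] * mu[2, lab[2]] * mu[3, lab[3]])
}

#' Normalize firing strengths
#'
#' @param w Nonnegative firing strengths.
#' @return `w / sum(w)`; signals a degenerate-activation condition when all
#'   strengths are zero.
#' @export
normalize_strengths <- function(w) {
  s <- sum(w)
  if (s <= 0) {
    abort("All rule firing strengths are zero (degenerate activation).",
          class = "fuzzyplan_error_degenerate")
  }
  w / s
}

# vectorized forward pass over an n x 3 input matrix (cols ptv, nt, oar);
# returns all layer outputs needed for inference and gradients
fuzzy_forward <- function(net, X) {
  X <- matrix(X, ncol = 3)
  n <- nrow(X)
  # memberships: n x 3 x 2
  mu <- array(0, c(n, 3, 2))
  for (k in 1:3) for (l in 1:2) {
    mu[, k, l] <- membership(X[, k], net$a[k, l], net$b[k, l])
  }
  li <- net$label_idx
  w <- matrix(1, n, 8)
  for (i in 1:8) for (k in 1:3) w[, i] <- w[, i] * mu[, k, li[i, k]]
  s <- rowSums(w)
  degenerate <- s <= 0
  s_safe <- ifelse(degenerate, 1, s)
  wbar <- w / s_safe
  wbar[degenerate, ] <- 1 / 8 # uniform fallback keeps the loop alive
  Z <- cbind(1, X) # n x 4
  fi <- Z %*% t(net$consequents) # n x 8
  f <- rowSums(wbar * fi)
  list(f = f, mu = mu, w = w, s = s, wbar = wbar, fi = fi, Z = Z,
       degenerate = degenerate)
}

#' Evaluate a fuzzy network on one input
#'
#' Runs the five layers: memberships (sigmoids), firing strengths (product),
#' normalization, first-order consequents, weighted sum. When every rule fires
#' with zero strength the normalized strengths fall back to the uniform 1/8
#' (the event is reported in the diagnostics and as a warning) so a planning
#' loop never halts mid-run.
#'
#' @param net A [fuzzy_network()].
#' @param x Named numeric input `c(ptv =, oar =, nt =)` of relative dose
#'   deviations.
#' @return List with crisp output `f` and diagnostics (`mu`, `w`, `wbar`,
#'   `fi`, `degenerate`).
#' @export
fuzzy_infer <- function(net, x) {
  stopifnot(all(c("ptv", "oar", "nt") %in% names(x)))
  fwd <- fuzzy_forward(net, matrix(x[INPUTS], 1))
  if (fwd$degenerate[1]) {
    warn("Degenerate rule activation: falling back to uniform strengths.",
         class = "fuzzyplan_warn_degenerate")
  }
  mu <- matrix(fwd$mu[1, , ], 3, 2, dimnames = list(INPUTS, LABELS))
  list(f = fwd$f[1], mu = mu, w = fwd$w[1, ], wbar = fwd$wbar[1, ],
       fi = fwd$fi[1, ], degenerate = fwd$degenerate[1])
}

#' Batch prediction over a tibble of dose deviations
#'
#' @param net A [fuzzy_network()].
#' @param data Data frame with columns `dd_ptv`, `dd_oar`, `dd_nt`.
#' @return The input tibble with a `.pred` column appended.
#' @export
fuzzy_predict <- function(net, data) {
  X <- cbind(data$dd_ptv, data$dd_nt, data$dd_oar)
  dplyr::mutate(as_tibble(data), .pred = fuzzy_forward(net, X)$f)
}

#' Static controller defaults
#'
#' Tunables of the untrained controller: `a0` is the sigmoid slope magnitude
#' (centers sit at zero; "low" uses slope `-a0`, "high" `+a0`), `delta_wf`
#' and `delta_pd` are the constant consequent magnitudes, i.e. the relative
#' move applied per iteration to weighting factors and prescription doses.
#'
#' @param a0 Slope magnitude (default 10).
#' @param delta_wf Constant consequent magnitude for weight networks (0.1).
#' @param delta_pd Constant consequent magnitude for prescription networks (0.05).
#' @return Named list of defaults.
#' @export
fis_defaults <- function(a0 = 10, delta_wf = 0.1, delta_pd = 0.05) {
  list(a0 = a0, delta_wf = delta_wf, delta_pd = delta_pd)
}

#' Static (untrained) fuzzy network for one plan parameter
#'
#' Encodes the planner heuristics: if the target dose is below its
#' prescription, raise the target weight (and push its prescription); if an
#' OAR or normal-tissue dose exceeds its prescription, raise that structure's
#' weight and tighten its prescription. Consequents are constants whose sign
#' follows the label of the structure the network drives.
#'
#' @param target One of `pd_ptv`, `pd_oar`, `pd_nt`, `wf_ptv`, `wf_oar`,
#'   `wf_nt`.
#' @param defaults Parameter defaults from [fis_defaults()].
#' @return A [fuzzy_network()].
#' @export
fis_network <- function(target, defaults = fis_defaults()) {
  target <- match.arg(target, TPP_TARGETS)
  a <- matrix(c(-defaults$a0, defaults$a0), 3, 2, byrow = TRUE,
              dimnames = list(INPUTS, LABELS))
  b <- matrix(0, 3, 2, dimnames = list(INPUTS, LABELS))
  rt <- rule_table_default()
  kind <- substr(target, 1, 2) # "pd" or "wf"
  structure_of <- sub("^(pd|wf)_", "", target)
  delta <- if (kind == "wf") defaults$delta_wf else defaults$delta_pd
  lab <- rt[, structure_of]
  # weights: push up when the driving structure violates its prescription
  # (target below it, OAR/NT above it); prescriptions move the opposite way
  # for OAR/NT (tighten when hot) and with the violation for the target.
  sign_violation <- if (structure_of == "ptv") {
    ifelse(lab == "low", 1, -1)
  } else {
    ifelse(lab == "high", 1, -1)
  }
  c0 <- if (kind == "wf") {
    delta * sign_violation
  } else if (structure_of == "ptv") {
    delta * sign_violation
  } else {
    -delta * sign_violation
  }
  consequents <- cbind(c0, 0, 0, 0)
  fuzzy_network(list(a = a, b = b), consequents, rt, target)
}

#' Full static controller: one network per plan parameter
#'
#' @param defaults See [fis_defaults()].
#' @return Named list of six [fuzzy_network()] objects.
#' @export
fis_network_set <- function(defaults = fis_defaults()) {
  setNames(lapply(TPP_TARGETS, fis_network, defaults = defaults), TPP_TARGETS)
}
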