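# Wild-type-versus-mutant difference profiles, summed-difference ranking,
# affected-region detection and additivity testing.

#' Difference profile between two residue profiles
#'
#' Per-residue differences `delta = reference - mutant` (so a positive
#' hnNOE or R2/R1 delta means the mutant is more mobile), with peak
#' pairing under the same doublet rules as CSP analysis. Errors are
#' combined in quadrature; the component errors and their plain sum are
#' kept so the alternative overlap criterion can be applied downstream.
#'
#' @param wt,mut `residue_profile`s with the same observable and salt
#'   condition (`wt` is the reference of the subtraction).
#' @return A data.frame of class `delta_profile`: `residue`, `pairing`,
#'   `delta`, `error` (quadrature), `error_sum` (sum of the two errors),
#'   `sigma_wt`, `sigma_mut`, `status`; attributes `observable`,
#'   `salt_mM`, `wt_construct`, `mut_construct`.
#' @export
delta_profile <- function(wt, mut) {
  if (profile_observable(wt) != profile_observable(mut))
    stop("observable mismatch: ", profile_observable(wt), " vs ",
         profile_observable(mut))
  if (profile_salt(wt) != profile_salt(mut))
    stop("salt-condition mismatch: ", profile_salt(wt), " vs ",
         profile_salt(mut), " mM")
  a <- wt[wt$status == "ok", , drop = FALSE]
  b <- mut[mut$status == "ok", , drop = FALSE]
  plan <- pair_peaks(a, b)

  rows <- lapply(seq_len(nrow(plan)), function(i) {
    if (plan$status[i] != "ok")
      return(data.frame(residue = plan$residue[i], pairing = NA_character_,
                        delta = NA_real_, error = NA_real_,
                        error_sum = NA_real_, sigma_wt = NA_real_,
                        sigma_mut = NA_real_, status = "missing"))
    x <- a[a$residue == plan$residue[i] & a$peak_id == plan$wt_peak[i], ]
    y <- b[b$residue == plan$residue[i] & b$peak_id == plan$mut_peak[i], ]
    data.frame(residue = plan$residue[i], pairing = plan$pairing[i],
               delta = x$value - y$value,
               error = sqrt(x$error^2 + y$error^2),
               error_sum = x$error + y$error,
               sigma_wt = x$error, sigma_mut = y$error, status = "ok")
  })
  rows <- do.call(rbind, rows)
  absent <- setdiff(seq_len(H3_TAIL_LENGTH), rows$residue)
  if (length(absent)) {
    rows <- rbind(rows, data.frame(
      residue = absent, pairing = NA_character_, delta = NA_real_,
      error = NA_real_, error_sum = NA_real_, sigma_wt = NA_real_,
      sigma_mut = NA_real_,
      status = vapply(absent, function(r) {
        if (r %in% invisible_positions()) "invisible" else "missing"
      }, character(1))))
  }
  rows <- rows[order(rows$residue), , drop = FALSE]
  rownames(rows) <- NULL
  structure(rows, class = c("delta_profile", "data.frame"),
            observable = profile_observable(wt),
            salt_mM = profile_salt(wt),
            wt_construct = profile_construct(wt),
            mut_construct = profile_construct(mut))
}

#' @export
print.delta_profile <- function(x, ...) {
  cat(sprintf("delta profile (%s, %g mM KCl): %s - %s\n",
              attr(x, "observable"), attr(x, "salt_mM"),
              attr(x, "wt_construct"), attr(x, "mut_construct")))
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}

# per-residue collapse: mean delta over pairings, error of that mean
collapse_deltas <- function(dp) {
  obs <- dp[dp$status == "ok", , drop = FALSE]
  if (!nrow(obs))
    return(data.frame(residue = integer(), delta = numeric(),
                      error = numeric(), sigma_wt = numeric(),
                      sigma_mut = numeric()))
  res <- sort(unique(obs$residue))
  out <- lapply(res, function(r) {
    g <- obs[obs$residue == r, , drop = FALSE]
    k <- nrow(g)
    data.frame(residue = r, delta = mean(g$delta),
               error = sqrt(sum(g$error^2)) / k,
               sigma_wt = sqrt(sum(g$sigma_wt^2)) / k,
               sigma_mut = sqrt(sum(g$sigma_mut^2)) / k)
  })
  do.call(rbind, out)
}

#' Summed difference across the tail
#'
#' Sum of the per-residue differences over all observed residues; doublet
#' residues contribute the mean of their pairing values, missing residues
#' contribute nothing. This is the "area between the profiles" statistic
#' used to rank mutants.
#'
#' @param profile a `delta_profile`.
#' @return Numeric scalar.
#' @export
summed_delta <- function(profile) {
  sum(collapse_deltas(profile)$delta)
}

#' Rank mutants by summed difference
#'
#' Orders difference profiles by decreasing [summed_delta()]. Exact ties
#' are broken by construct name for determinism and flagged.
#'
#' @param profiles named list of `delta_profile`s sharing observable and
#'   salt condition.
#' @return A data.frame `construct`, `summed_delta`, `rank`, `tie`.
#' @export
rank_mutants <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  obs <- vapply(profiles, function(p) attr(p, "observable"), character(1))
  salt <- vapply(profiles, function(p) attr(p, "salt_mM"), numeric(1))
  if (length(unique(obs)) != 1L)
    stop("profiles mix observables: ", paste(unique(obs), collapse = ", "))
  if (length(unique(salt)) != 1L)
    stop("profiles mix salt conditions")
  cons <- names(profiles) %||%
    vapply(profiles, function(p) attr(p, "mut_construct"), character(1))
  sums <- vapply(profiles, summed_delta, numeric(1))
  ord <- order(-sums, cons)
  out <- data.frame(construct = cons[ord], summed_delta = sums[ord],
                    rank = seq_along(ord))
  out$tie <- duplicated(out$summed_delta) |
    duplicated(out$summed_delta, fromLast = TRUE)
  rownames(out) <- NULL
  out
}

# ---- affected-region detection ---------------------------------------------

# qualification per residue: at least one pairing with |delta| strictly
# above k * error (criterion "quadrature" uses the quadrature-combined
# error; "halfwidth-sum" uses the sum of the two component errors)
qualifies_by_residue <- function(dp, k = 1,
                                 criterion = c("quadrature", "halfwidth-sum")) {
  criterion <- match.arg(criterion)
  q <- rep(NA, H3_TAIL_LENGTH)           # NA = unobserved
  obs <- dp[dp$status == "ok", , drop = FALSE]
  err <- if (criterion == "quadrature") obs$error else obs$error_sum
  hit <- abs(obs$delta) > k * err
  for (r in unique(obs$residue))
    q[r] <- any(hit[obs$residue == r])
  q
}

#' Detect regions affected by a mutation
#'
#' Implements the run rule used to assess the breadth of a mutation's
#' effect: a region is a string of at least three qualifying residues —
#' residues whose |delta| strictly exceeds `k` times the combined error
#' for at least one peak pairing — where single observed non-qualifying
#' residues may interrupt the run but two in a row break it. Unobserved
#' residues (prolines, omitted residues) neither qualify nor break a run,
#' and are counted in the inclusive span. Region endpoints must qualify.
#'
#' @param profile a `delta_profile`.
#' @param k error-bar multiple (default 1).
#' @param criterion `"quadrature"` combines the two profiles' errors in
#'   quadrature (statistical convention); `"halfwidth-sum"` uses the sum
#'   of the two error-bar half-widths (the literal non-overlap of plotted
#'   error bars).
#' @return A data.frame of regions in N-to-C order: `start`, `end`
#'   (positions), `start_label`, `end_label`, `residue_count` (inclusive
#'   positional count), `n_qualifying`, `interruptions` (comma-separated
#'   interrupting positions, `""` if none).
#' @examples
#' \dontrun{
#' detect_affected_regions(dp, k = 1)
#' }
#' @export
detect_affected_regions <- function(profile, k = 1,
                                    criterion = c("quadrature",
                                                  "halfwidth-sum")) {
  q <- qualifies_by_residue(profile, k, match.arg(criterion))
  qual_pos <- which(!is.na(q) & q)
  empty <- data.frame(start = integer(), end = integer(),
                      start_label = character(), end_label = character(),
                      residue_count = integer(), n_qualifying = integer(),
                      interruptions = character())
  if (!length(qual_pos)) return(empty)

  # split the qualifying positions where more than one observed
  # non-qualifying residue lies between neighbours
  runs <- list()
  current <- qual_pos[1]
  for (p in qual_pos[-1]) {
    gap <- seq(current[length(current)] + 1L, p - 1L)
    n_bad <- if (length(gap) && gap[1] <= gap[length(gap)])
      sum(!is.na(q[gap]) & !q[gap]) else 0L
    if (n_bad <= 1L) current <- c(current, p)
    else { runs[[length(runs) + 1L]] <- current; current <- p }
  }
  runs[[length(runs) + 1L]] <- current
  runs <- Filter(function(r) length(r) >= 3L, runs)
  if (!length(runs)) return(empty)

  out <- lapply(runs, function(r) {
    s <- r[1]; e <- r[length(r)]
    span <- s:e
    inter <- span[!is.na(q[span]) & !q[span]]
    data.frame(start = s, end = e,
               start_label = residue_label(s), end_label = residue_label(e),
               residue_count = count_residue_range(s, e),
               n_qualifying = length(r),
               interruptions = paste(inter, collapse = ","))
  })
  do.call(rbind, out)
}

#' Additivity of single-mutant effects
#'
#' Compares the sum of the four single-arginine-mutant difference profiles
#' with the quadruple-mutant difference profile, per residue over the
#' intersection of observed residues. The discrepancy is
#' `sum(singles) - quadruple`; its combined error by default propagates
#' the shared wild-type reference correctly (the wild-type value enters
#' the discrepancy three times), with the naive quadrature of the five
#' delta errors available for comparison.
#'
#' @param singles list of four `delta_profile`s (single mutants).
#' @param quadruple the quadruple-mutant `delta_profile`.
#' @param error_mode `"propagated"` (default) or `"quadrature"`.
#' @return A data.frame `residue`, `discrepancy`, `error`, `within`
#'   (|discrepancy| < error); attributes `mean_abs_discrepancy`,
#'   `fraction_within`.
#' @export
additivity_discrepancy <- function(singles, quadruple,
                                   error_mode = c("propagated",
                                                  "quadrature")) {
  error_mode <- match.arg(error_mode)
  if (length(singles) != 4L)
    stop("additivity test needs the four single-mutant profiles")
  all_p <- c(singles, list(quadruple))
  obs <- unique(vapply(all_p, function(p) attr(p, "observable"), character(1)))
  salt <- unique(vapply(all_p, function(p) attr(p, "salt_mM"), numeric(1)))
  if (length(obs) != 1L || length(salt) != 1L)
    stop("profiles must share observable and salt condition")

  coll <- lapply(all_p, collapse_deltas)
  common <- sort(Reduce(intersect, lapply(coll, `[[`, "residue")))
  if (!length(common)) stop("no residues observed in all five profiles")

  rows <- lapply(common, function(r) {
    g <- lapply(coll, function(d) d[d$residue == r, ])
    ds <- vapply(g, `[[`, numeric(1), "delta")
    disc <- sum(ds[1:4]) - ds[5]
    if (error_mode == "quadrature") {
      err <- sqrt(sum(vapply(g, `[[`, numeric(1), "error")^2))
    } else {
      swt <- vapply(g, `[[`, numeric(1), "sigma_wt")
      smu <- vapply(g, `[[`, numeric(1), "sigma_mut")
      # discrepancy = 3*WT - sum(single mutants) + quad
      err <- sqrt(9 * mean(swt)^2 + sum(smu^2))
    }
    data.frame(residue = r, discrepancy = disc, error = err,
               within = abs(disc) < err)
  })
  out <- do.call(rbind, rows)
  structure(out,
            mean_abs_discrepancy = mean(abs(out$discrepancy)),
            fraction_within = mean(out$within),
            observable = obs, salt_mM = salt)
}

#' Percent change between two values
#'
#' `100 * (new - reference) / reference`, signed and unrounded.
#' [render_percent_change()] formats the nearest-integer magnitude for
#' report text, e.g. `"17% increase"`.
#'
#' @param reference,new numeric values; `reference` must be non-zero.
#' @return Signed percent change.
#' @examples
#' percent_change(1.07, 1.25)                  # +16.82...
#' render_percent_change(percent_change(21, 8)) # "62% decrease"
#' @export
percent_change <- function(reference, new) {
  if (any(reference == 0)) stop("undefined percent change: reference is zero")
  100 * (new - reference) / reference
}

#' @rdname percent_change
#' @param pct a percent change as returned by [percent_change()].
#' @export
render_percent_change <- function(pct) {
  sprintf("%d%% %s", round(abs(pct)),
          ifelse(pct >= 0, "increase", "decrease"))
}
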