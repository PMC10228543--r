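# Per-residue observable profiles built from peak tables.
#
# A residue_profile accounts for every tail position 1-36: either one row
# per fitted peak (status "ok") or one row with NA value and a reason
# ("invisible", "omitted", "not-observed", "not-fit").

new_residue_profile <- function(rows, construct, salt_mM, observable) {
  rows <- rows[order(rows$residue, rows$peak_id), , drop = FALSE]
  rownames(rows) <- NULL
  structure(rows, class = c("residue_profile", "data.frame"),
            construct = construct, salt_mM = salt_mM, observable = observable)
}

profile_observable <- function(x) attr(x, "observable")
profile_construct <- function(x) attr(x, "construct")
profile_salt <- function(x) attr(x, "salt_mM")

#' @export
print.residue_profile <- function(x, ...) {
  cat(sprintf("%s profile: %s at %g mM KCl (%d observed peaks)\n",
              profile_observable(x), profile_construct(x), profile_salt(x),
              sum(x$status == "ok")))
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}

# rows for the residues with no data, carrying the omission reason
missing_rows <- function(present, construct, salt_mM,
                         experiment = "relaxation", reason_override = NULL) {
  miss <- setdiff(seq_len(H3_TAIL_LENGTH), present)
  if (!length(miss)) return(NULL)
  data.frame(residue = miss, peak_id = NA_integer_, value = NA_real_,
             error = NA_real_,
             status = vapply(miss, function(r) {
               reason_override %||%
                 missing_reason(r, construct, salt_mM, experiment)
             }, character(1)))
}

single_table_meta <- function(peaks) {
  construct <- unique(peaks$construct)
  salt <- unique(peaks$salt_mM)
  if (length(construct) != 1L || length(salt) != 1L)
    stop("peak table must contain a single (construct, salt) sample")
  list(construct = construct, salt_mM = salt)
}

#' Per-residue relaxation-rate profile
#'
#' Fits every (residue, peak) decay series in a peak table with
#' [fit_exponential()] and assembles a profile with the fitted rate and
#' its error. Residues whose fit fails are flagged `"not-fit"`; absent
#' residues carry the observability reason.
#'
#' @param peaks a peak-table data.frame (see [simulate_peak_table()] or
#'   [read_peak_table()]) for one (construct, salt) sample.
#' @param experiment `"R1"` or `"R2"`.
#' @param error_scaling passed to [fit_exponential()].
#' @return A `residue_profile` data.frame: `residue`, `peak_id`, `value`,
#'   `error`, `status`.
#' @export
relaxation_profile <- function(peaks, experiment = c("R1", "R2"),
                               error_scaling = c("residual", "noise")) {
  experiment <- match.arg(experiment)
  error_scaling <- match.arg(error_scaling)
  meta <- single_table_meta(peaks)
  sub <- peaks[peaks$experiment == experiment, , drop = FALSE]
  groups <- unique(sub[, c("residue", "peak_id")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- sub[sub$residue == groups$residue[i] &
             sub$peak_id == groups$peak_id[i], , drop = FALSE]
    fit <- fit_exponential(g$delay_s, g$intensity, noise = g$noise[1],
                           error_scaling = error_scaling)
    data.frame(residue = groups$residue[i], peak_id = groups$peak_id[i],
               value = if (fit$ok) fit$rate else NA_real_,
               error = if (fit$ok) fit$rate_error else NA_real_,
               status = if (fit$ok) "ok" else "not-fit")
  })
  rows <- do.call(rbind, c(rows, list(
    missing_rows(groups$residue, meta$construct, meta$salt_mM))))
  new_residue_profile(rows, meta$construct, meta$salt_mM, experiment)
}

#' Per-residue heteronuclear NOE profile
#'
#' Matches saturated and reference rows per (residue, peak) and applies
#' [compute_hnnoe()].
#'
#' @inheritParams relaxation_profile
#' @return A `residue_profile` with observable `"hnNOE"`.
#' @export
noe_profile <- function(peaks) {
  meta <- single_table_meta(peaks)
  sat <- peaks[peaks$experiment == "hnNOE-sat", , drop = FALSE]
  ref <- peaks[peaks$experiment == "hnNOE-ref", , drop = FALSE]
  groups <- unique(rbind(sat[, c("residue", "peak_id")],
                         ref[, c("residue", "peak_id")]))
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    s <- sat[sat$residue == groups$residue[i] &
             sat$peak_id == groups$peak_id[i], , drop = FALSE]
    r <- ref[ref$residue == groups$residue[i] &
             ref$peak_id == groups$peak_id[i], , drop = FALSE]
    if (nrow(s) != 1L || nrow(r) != 1L || r$intensity == 0) {
      return(data.frame(residue = groups$residue[i],
                        peak_id = groups$peak_id[i], value = NA_real_,
                        error = NA_real_, status = "not-fit"))
    }
    v <- compute_hnnoe(s$intensity, r$intensity, s$noise, r$noise)
    data.frame(residue = groups$residue[i], peak_id = groups$peak_id[i],
               value = v$value, error = v$error, status = "ok")
  })
  rows <- do.call(rbind, c(rows, list(
    missing_rows(groups$residue, meta$construct, meta$salt_mM))))
  new_residue_profile(rows, meta$construct, meta$salt_mM, "hnNOE")
}

#' Per-residue R2/R1 profile
#'
#' Combines matching peaks of an R1 and an R2 profile via
#' [compute_r2_over_r1()]. Peaks fit in only one of the two experiments
#' are flagged `"not-fit"`.
#'
#' @param r1,r2 `residue_profile`s with observables `"R1"` and `"R2"`
#'   from the same sample.
#' @return A `residue_profile` with observable `"R2R1"`.
#' @export
ratio_profile <- function(r1, r2) {
  stopifnot(profile_observable(r1) == "R1", profile_observable(r2) == "R2")
  if (profile_construct(r1) != profile_construct(r2) ||
      profile_salt(r1) != profile_salt(r2))
    stop("R1 and R2 profiles come from different samples")
  keys <- unique(rbind(r1[r1$status == "ok", c("residue", "peak_id")],
                       r2[r2$status == "ok", c("residue", "peak_id")]))
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    a <- r1[r1$residue == keys$residue[i] & !is.na(r1$peak_id) &
            r1$peak_id == keys$peak_id[i], , drop = FALSE]
    b <- r2[r2$residue == keys$residue[i] & !is.na(r2$peak_id) &
            r2$peak_id == keys$peak_id[i], , drop = FALSE]
    if (nrow(a) != 1L || nrow(b) != 1L ||
        a$status != "ok" || b$status != "ok") {
      return(data.frame(residue = keys$residue[i], peak_id = keys$peak_id[i],
                        value = NA_real_, error = NA_real_,
                        status = "not-fit"))
    }
    v <- compute_r2_over_r1(a$value, b$value, a$error, b$error)
    data.frame(residue = keys$residue[i], peak_id = keys$peak_id[i],
               value = v$value, error = v$error, status = "ok")
  })
  rows <- do.call(rbind, c(rows, list(
    missing_rows(keys$residue, profile_construct(r1), profile_salt(r1)))))
  new_residue_profile(rows, profile_construct(r1), profile_salt(r1), "R2R1")
}

#' Unweighted region average of a profile
#'
#' Mean and sample standard deviation of the observed values in an
#' inclusive residue span. Doublet residues contribute the mean of their
#' two peak values as a single observation; missing residues are excluded
#' from `n`.
#'
#' @param profile a `residue_profile`.
#' @param start,end residue labels, positions or `residue_id`s.
#' @return List with `mean`, `sd` (NA when `n = 1`) and `n`.
#' @examples
#' \dontrun{
#' region_average(noe, "S28", "K36")
#' }
#' @export
region_average <- function(profile, start, end) {
  s <- as_residue_id(start)$position
  e <- as_residue_id(end)$position
  if (s > e) stop("range start comes after end")
  obs <- profile[profile$status == "ok" & profile$residue >= s &
                 profile$residue <= e, , drop = FALSE]
  if (!nrow(obs))
    stop("empty region: no observed residues in span ",
         format(as_residue_id(start)), "-", format(as_residue_id(end)))
  per_res <- tapply(obs$value, obs$residue, mean)
  list(mean = mean(per_res), sd = if (length(per_res) > 1) sd(per_res)
       else NA_real_, n = length(per_res))
}
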