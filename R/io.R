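# Study orchestration: configuration, simulation and end-to-end analysis.

STUDY_CONSTRUCTS <- c("WT", "R2Q", "R8Q", "R17Q", "R26Q", "R2/8/17/26Q")

#' Run configuration for a synthetic study
#'
#' Collects everything a reproducible run needs: constructs, salt
#' conditions, noise level, anchor-model parameter overrides, the
#' error-bar overlap criterion, and an explicit seed (there are no
#' wall-clock defaults anywhere).
#'
#' @param constructs construct labels; defaults to the six-study set
#'   (wild type, four single arginine mutants, the quadruple mutant).
#' @param salts_mM KCl conditions, a subset of `c(0, 150)`.
#' @param noise_fraction per-spectrum noise as a fraction of the
#'   reference intensity.
#' @param seed integer seed for all randomness in the run.
#' @param params an [anchor_params()] object.
#' @param overlap_criterion `"quadrature"` or `"halfwidth-sum"`, passed to
#'   [detect_affected_regions()].
#' @param region_k error-bar multiple for region detection.
#' @return A list of class `run_config`.
#' @export
run_config <- function(constructs = STUDY_CONSTRUCTS,
                       salts_mM = c(0, 150),
                       noise_fraction = NULL,
                       seed = 1L,
                       params = anchor_params(),
                       overlap_criterion = c("quadrature", "halfwidth-sum"),
                       region_k = 1) {
  for (cn in constructs) parse_construct(cn)
  for (s in salts_mM) check_salt(s)
  structure(list(constructs = constructs, salts_mM = salts_mM,
                 noise_fraction = noise_fraction %||% params$noise_fraction,
                 seed = as.integer(seed), params = params,
                 overlap_criterion = match.arg(overlap_criterion),
                 region_k = region_k),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognized keys: `constructs`, `salts_mM`, `noise_fraction`, `seed`,
#' `overlap_criterion`, `region_k`, and `params` (a mapping of
#' [anchor_params()] overrides). Missing keys fall back to the defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @examples
#' cfg <- read_run_config(system.file("extdata", "example_config.yaml",
#'                                    package = "tailspin"))
#' cfg$seed
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  par_over <- y$params %||% list()
  params <- do.call(anchor_params, par_over)
  run_config(constructs = y$constructs %||% STUDY_CONSTRUCTS,
             salts_mM = y$salts_mM %||% c(0, 150),
             noise_fraction = y$noise_fraction,
             seed = y$seed %||% 1L,
             params = params,
             overlap_criterion = y$overlap_criterion %||% "quadrature",
             region_k = y$region_k %||% 1)
}

sanitize_construct <- function(construct) gsub("/", "-", construct, fixed = TRUE)

peak_table_filename <- function(construct, salt_mM)
  sprintf("peaks_%s_%gmM.tsv", sanitize_construct(construct), salt_mM)

#' Simulate a full study to disk
#'
#' Writes one peak table per (construct, salt) plus a YAML manifest
#' recording the parameters, seed and package version. Re-running with the
#' same configuration reproduces the files byte for byte.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the paths of the written tables.
#' @export
simulate_study <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (salt in config$salts_mM) {
    for (cn in config$constructs) {
      variant <- if (cn == "WT" && salt == 150) "wt150" else "default"
      tab <- simulate_peak_table(cn, salt, config$params, config$seed,
                                 noise_fraction = config$noise_fraction,
                                 r2_variant = variant)
      p <- file.path(out_dir, peak_table_filename(cn, salt))
      write_peak_table(tab, p)
      paths <- c(paths, p)
    }
  }
  manifest <- list(
    seed = config$seed,
    constructs = config$constructs,
    salts_mM = config$salts_mM,
    noise_fraction = config$noise_fraction,
    overlap_criterion = config$overlap_criterion,
    region_k = config$region_k,
    params = lapply(unclass(config$params), function(v)
      if (is.numeric(v)) as.list(setNames(as.numeric(v), names(v))) else v),
    tool_version = as.character(packageVersion("tailspin")))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  message("wrote ", length(paths), " peak tables to ", out_dir)
  invisible(paths)
}

build_profiles <- function(tab) {
  r1 <- relaxation_profile(tab, "R1")
  r2 <- relaxation_profile(tab, "R2")
  list(R1 = r1, R2 = r2, hnNOE = noe_profile(tab),
       R2R1 = ratio_profile(r1, r2))
}

profiles_to_df <- function(profs, construct, salt) {
  do.call(rbind, lapply(names(profs), function(obs) {
    p <- profs[[obs]]
    data.frame(construct = construct, salt_mM = salt, observable = obs,
               residue = p$residue, peak_id = p$peak_id, value = p$value,
               error = p$error, status = p$status)
  }))
}

#' Analyze a simulated or imported study end to end
#'
#' Reads the peak tables of `tables_dir`, fits all relaxation profiles,
#' computes CSPs against wild type, builds difference profiles (hnNOE and
#' R2/R1), detects affected regions, ranks mutants by summed difference,
#' runs the additivity test (when all four singles and the quadruple are
#' present), and writes CSV reports plus a plain-text summary. Comparison
#' stages that lack the needed constructs are skipped with a notice.
#'
#' @param config a [run_config()] (controls the overlap criterion and
#'   which constructs/salts to look for).
#' @param tables_dir directory holding the peak tables (see
#'   [simulate_study()]).
#' @param out_dir directory for the reports; defaults to `tables_dir`.
#' @return Invisibly, a list with all in-memory results (`profiles`,
#'   `csp`, `deltas`, `regions`, `ranking`, `additivity`).
#' @export
analyze_study <- function(config, tables_dir, out_dir = tables_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  profiles <- list(); tables <- list()
  prof_df <- list()
  for (salt in config$salts_mM) {
    for (cn in config$constructs) {
      p <- file.path(tables_dir, peak_table_filename(cn, salt))
      if (!file.exists(p)) stop("missing peak table: ", p)
      tab <- read_peak_table(p)
      key <- paste(cn, salt, sep = "@")
      tables[[key]] <- tab
      profiles[[key]] <- build_profiles(tab)
      prof_df[[key]] <- profiles_to_df(profiles[[key]], cn, salt)
    }
  }
  write.csv(do.call(rbind, prof_df), file.path(out_dir, "profiles.csv"),
            row.names = FALSE)

  mutants <- setdiff(config$constructs, "WT")
  has_wt <- "WT" %in% config$constructs
  csp_all <- list(); delta_list <- list(); region_df <- list()
  rank_df <- list(); addi_df <- list()

  if (!has_wt || !length(mutants)) {
    message("comparison stages skipped: need WT plus at least one mutant")
  } else {
    for (salt in config$salts_mM) {
      wt_key <- paste("WT", salt, sep = "@")
      for (cn in mutants) {
        key <- paste(cn, salt, sep = "@")
        cp <- csp_profile(tables[[wt_key]], tables[[key]])
        csp_all[[key]] <- data.frame(construct = cn, salt_mM = salt,
                                     as.data.frame(cp))
      }
      for (obs in c("hnNOE", "R2R1")) {
        dps <- lapply(mutants, function(cn)
          delta_profile(profiles[[wt_key]][[obs]],
                        profiles[[paste(cn, salt, sep = "@")]][[obs]]))
        names(dps) <- mutants
        delta_list[[paste(obs, salt, sep = "@")]] <- dps
        for (cn in mutants) {
          regs <- detect_affected_regions(dps[[cn]], config$region_k,
                                          config$overlap_criterion)
          if (nrow(regs))
            region_df[[paste(cn, obs, salt)]] <-
              data.frame(construct = cn, observable = obs, salt_mM = salt,
                         regs)
          else
            region_df[[paste(cn, obs, salt)]] <-
              data.frame(construct = cn, observable = obs, salt_mM = salt,
                         start = NA_integer_, end = NA_integer_,
                         start_label = NA_character_,
                         end_label = NA_character_,
                         residue_count = 0L, n_qualifying = 0L,
                         interruptions = "")
        }
        if (length(mutants) >= 2L) {
          rk <- rank_mutants(dps)
          rank_df[[paste(obs, salt)]] <-
            data.frame(observable = obs, salt_mM = salt, rk)
        }
        singles <- intersect(c("R2Q", "R8Q", "R17Q", "R26Q"), mutants)
        if (length(singles) == 4L && "R2/8/17/26Q" %in% mutants) {
          ad <- additivity_discrepancy(dps[singles], dps[["R2/8/17/26Q"]])
          addi_df[[paste(obs, salt)]] <-
            data.frame(observable = obs, salt_mM = salt, as.data.frame(ad),
                       mean_abs_discrepancy = attr(ad, "mean_abs_discrepancy"),
                       fraction_within = attr(ad, "fraction_within"))
        } else {
          message("additivity test skipped at ", salt,
                  " mM: needs all four single mutants and the quadruple")
        }
      }
    }
    if (length(csp_all))
      write.csv(do.call(rbind, csp_all), file.path(out_dir, "csp.csv"),
                row.names = FALSE)
    deltas_flat <- do.call(rbind, lapply(names(delta_list), function(k) {
      dps <- delta_list[[k]]
      do.call(rbind, lapply(names(dps), function(cn) {
        d <- dps[[cn]]
        data.frame(construct = cn, observable = attr(d, "observable"),
                   salt_mM = attr(d, "salt_mM"), as.data.frame(d))
      }))
    }))
    write.csv(deltas_flat, file.path(out_dir, "deltas.csv"),
              row.names = FALSE)
    if (length(region_df))
      write.csv(do.call(rbind, region_df), file.path(out_dir, "regions.csv"),
                row.names = FALSE)
    if (length(rank_df))
      write.csv(do.call(rbind, rank_df), file.path(out_dir, "ranking.csv"),
                row.names = FALSE)
    if (length(addi_df))
      write.csv(do.call(rbind, addi_df), file.path(out_dir, "additivity.csv"),
                row.names = FALSE)
  }

  writeLines(study_summary(profiles, region_df, rank_df, config),
             file.path(out_dir, "summary.txt"))
  invisible(list(profiles = profiles, csp = csp_all, deltas = delta_list,
                 regions = if (length(region_df)) do.call(rbind, region_df),
                 ranking = if (length(rank_df)) do.call(rbind, rank_df),
                 additivity = addi_df))
}

# plain-text headline summary of a study
study_summary <- function(profiles, region_df, rank_df, config) {
  out <- c("tailspin study summary", "======================", "")
  for (salt in config$salts_mM) {
    wt_key <- paste("WT", salt, sep = "@")
    if (!wt_key %in% names(profiles)) next
    pf <- profiles[[wt_key]]
    noe_all <- region_average(pf$hnNOE, "T3", "K36")
    noe_nt <- region_average(pf$hnNOE, "T3", "K27")
    noe_hinge <- region_average(pf$hnNOE, "S28", "K36")
    r1m <- region_average(pf$R1, "T3", "K36")
    r2m <- region_average(pf$R2, "T3", "K36")
    out <- c(out, sprintf("WT at %g mM KCl:", salt),
             sprintf("  mean hnNOE %.2f +/- %.2f (n = %d); T3-K27 %.2f, hinge S28-K36 %.2f",
                     noe_all$mean, noe_all$sd, noe_all$n, noe_nt$mean,
                     noe_hinge$mean),
             sprintf("  mean R1 %.2f s^-1, mean R2 %.1f s^-1",
                     r1m$mean, r2m$mean))
    quad_key <- paste("R2/8/17/26Q", salt, sep = "@")
    if (quad_key %in% names(profiles)) {
      qf <- profiles[[quad_key]]
      qr1 <- region_average(qf$R1, "T3", "K36")
      qnoe <- region_average(qf$hnNOE, "T3", "K36")
      out <- c(out, sprintf(
        "  quadruple mutant: mean hnNOE %.2f (%s), mean R1 %.2f s^-1 (%s)",
        qnoe$mean, render_percent_change(percent_change(noe_all$mean,
                                                        qnoe$mean)),
        qr1$mean, render_percent_change(percent_change(r1m$mean, qr1$mean))))
    }
    out <- c(out, "")
  }
  if (length(rank_df)) {
    out <- c(out, "summed-difference ranking (WT - mutant):")
    for (k in names(rank_df)) {
      rk <- rank_df[[k]]
      out <- c(out, sprintf("  %s at %g mM: %s", rk$observable[1],
                            rk$salt_mM[1],
                            paste(rk$construct, collapse = " > ")))
    }
    out <- c(out, "")
  }
  if (length(region_df)) {
    out <- c(out, "affected regions (>= 3 qualifying residues):")
    for (k in names(region_df)) {
      r <- region_df[[k]]
      r <- r[!is.na(r$start), , drop = FALSE]
      if (!nrow(r)) next
      out <- c(out, sprintf("  %s %s %g mM: %s", r$construct[1],
                            r$observable[1], r$salt_mM[1],
                            paste(sprintf("%s-%s (%d residues)",
                                          r$start_label, r$end_label,
                                          r$residue_count),
                                  collapse = ", ")))
    }
  }
  out
}

#' Read a Sparky-style peak list
#'
#' Convenience importer for peak lists with columns `assignment, w1, w2,
#' height` (w1 = 15N ppm, w2 = 1H ppm), with assignments like `T22N-H`.
#' Returns rows in the package's peak-table layout (experiment `"HSQC"`).
#'
#' @param path file path.
#' @param construct,salt_mM sample metadata to stamp on the rows.
#' @return A peak-table data.frame.
#' @examples
#' read_sparky(system.file("extdata", "example_sparky.list",
#'                         package = "tailspin"))
#' @export
read_sparky <- function(path, construct = "WT", salt_mM = 0) {
  raw <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("assignment", "w1", "w2")
  names(raw) <- tolower(names(raw))
  if (!all(need %in% names(raw)))
    stop("Sparky list needs columns assignment, w1, w2 (and optionally height)")
  res <- vapply(raw$assignment, function(a) {
    m <- regmatches(a, regexec("^([A-Za-z])([0-9]+)", a))[[1]]
    if (length(m) != 3L) stop("unparseable assignment: ", a)
    as.integer(m[3])
  }, integer(1))
  peak_id <- stats::ave(res, res, FUN = seq_along)
  data.frame(construct = construct, salt_mM = salt_mM, experiment = "HSQC",
             residue = res, peak_id = as.integer(peak_id),
             delay_s = NA_real_,
             intensity = if ("height" %in% names(raw)) raw$height
                         else NA_real_,
             noise = NA_real_, dH_ppm = raw$w2, dN_ppm = raw$w1)
}
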