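# Coformer screening: the lattice-energy difference ddU between the best
# cocrystal structure and the stoichiometric sum of the best neat-component
# structures, with a fusion free-energy correction for coformers that are
# liquid at the screening temperature, ranked and classified by threshold.

#' Fusion data for a (possibly liquid) coformer
#'
#' @param T_fus melting temperature in K (> 0).
#' @param dH_fus enthalpy of fusion at the melting point in kJ/mol (>= 0).
#' @param T screening temperature in K (default 300, room temperature).
#' @return An object of class `ccs_fusion`.
#' @export
fusion_data <- function(T_fus, dH_fus, T = 300) {
  stopifnot(T_fus > 0, dH_fus >= 0, T > 0)
  structure(list(T_fus = T_fus, dH_fus = dH_fus, T = T), class = "ccs_fusion")
}

#' Liquid-coformer fusion correction
#'
#' For a coformer that is liquid at the screening temperature `T > T_fus`,
#' the cocrystal is a solvate and the stability difference must account for
#' the free energy of fusion, approximated from the melting-point enthalpy as
#' `dG_fus(T) = dH_fus * (1 - T / T_fus)` (negative above the melting point).
#' The additive shift applied to ddU is `-m * dG_fus`, i.e. positive when the
#' coformer is liquid: crystallising a liquid costs free energy, making the
#' solvate look correspondingly less favourable. The alternative ideal-gas
#' style `3/2 RT` estimate per coformer molecule is available as
#' `policy = "rt"`.
#'
#' @param f a [fusion_data()].
#' @param m stoichiometric count of the coformer in the cocrystal formula.
#' @param policy `"fusion"` (default, enthalpy-of-fusion based) or `"rt"`
#'   (`3/2 R T` per coformer molecule).
#' @return `list(dG_fus = kJ/mol, shift = kJ/mol)`; `shift` is 0 with a
#'   message when the coformer is solid at `T` (`T <= T_fus`).
#' @export
fusion_correction <- function(f, m = 1, policy = c("fusion", "rt")) {
  policy <- match.arg(policy)
  dG <- f$dH_fus * (1 - f$T / f$T_fus)
  if (f$T <= f$T_fus) {
    if (f$T < f$T_fus)
      message("coformer is solid at ", f$T,
              " K (T_fus = ", f$T_fus, " K); no fusion correction applied")
    return(list(dG_fus = if (f$T == f$T_fus) 0 else dG, shift = 0))
  }
  shift <- if (policy == "rt") m * 1.5 * 8.31446261815324e-3 * f$T else -m * dG
  list(dG_fus = dG, shift = shift)
}

#' Lattice-energy difference for one API/coformer pair
#'
#' `ddU = U_cc - n * U_API - m * U_c`, in kJ/mol per cocrystal formula, plus
#' the fusion shift when fusion data are supplied and the coformer is liquid
#' at the screening temperature. Negative values favour cocrystallisation.
#'
#' @param U_cc lattice energy of the best cocrystal structure (kJ/mol per
#'   formula, i.e. per `n` API + `m` coformer molecules).
#' @param U_api,U_c best neat lattice energies (kJ/mol per molecule).
#' @param n,m stoichiometry of the cocrystal `API_n c_m`.
#' @param fusion optional [fusion_data()] for the coformer.
#' @param hash_cc,hash_api,hash_c optional potential-parameter-set hashes;
#'   if given they must all agree (energies from different parameter sets are
#'   not comparable).
#' @param fusion_policy passed to [fusion_correction()].
#' @return ddU in kJ/mol, with attribute `correction` (the applied shift).
#' @export
delta_delta_U <- function(U_cc, U_api, U_c, n = 1, m = 1, fusion = NULL,
                          hash_cc = NULL, hash_api = NULL, hash_c = NULL,
                          fusion_policy = "fusion") {
  hashes <- unique(unlist(list(hash_cc, hash_api, hash_c)))
  if (length(hashes) > 1)
    stop("parameter-set hash mismatch: lattice energies are not comparable")
  dd <- U_cc - n * U_api - m * U_c
  corr <- 0
  if (!is.null(fusion) && fusion$T > fusion$T_fus)
    corr <- fusion_correction(fusion, m, policy = fusion_policy)$shift
  out <- dd + corr
  attr(out, "correction") <- corr
  out
}

#' Rank screening entries by increasing ddU
#'
#' Stable ascending sort on `ddU`, ties broken lexicographically by coformer
#' identifier; 1-based ranks are assigned.
#'
#' @param entries data.frame with at least `coformer` and `ddU` columns.
#' @return The data.frame reordered with a `rank` column.
#' @export
rank_coformers <- function(entries) {
  ord <- order(entries$ddU, entries$coformer)
  out <- entries[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Threshold classification of screening entries
#'
#' A coformer is excluded iff its ddU strictly exceeds the threshold
#' (a value *exceeding* the cutoff makes a cocrystal unlikely; equality is
#' retained). Presets: `"screening"` uses +5 kJ/mol, `"strict"` uses 0.
#'
#' @param entries ranked data.frame with a `ddU` column.
#' @param threshold numeric cutoff in kJ/mol, or a preset name.
#' @return The data.frame with a `classification` column
#'   (`"retain"`/`"exclude"`).
#' @export
classify <- function(entries, threshold = "screening") {
  if (is.character(threshold))
    threshold <- switch(match.arg(threshold, c("screening", "strict")),
                        screening = 5, strict = 0)
  entries$classification <- ifelse(entries$ddU > threshold, "exclude", "retain")
  attr(entries, "threshold") <- threshold
  entries
}

#' Screening-efficiency statistics
#'
#' Exclusion percentage (share of coformers with ddU above the threshold) and
#' hit percentage (share of retained coformers that were experimentally
#' observed to form cocrystals), rounded to the nearest integer.
#'
#' @param entries data.frame with `ddU` and logical `observed` columns.
#' @param threshold exclusion cutoff in kJ/mol (default 5).
#' @return `list(exclusion_pct, hit_pct, n, n_excluded, n_retained)`;
#'   `hit_pct` is `NA` when nothing is retained.
#' @export
screening_stats <- function(entries, threshold = 5) {
  n <- nrow(entries)
  excluded <- entries$ddU > threshold
  retained <- !excluded
  hit <- if (sum(retained) == 0) NA_real_ else
    round(100 * sum(retained & entries$observed) / sum(retained))
  list(exclusion_pct = round(100 * sum(excluded) / n),
       hit_pct = hit, n = n, n_excluded = sum(excluded),
       n_retained = sum(retained))
}

#' Run a full coformer screen
#'
#' Executes the screening algorithm end to end: (1) build or load the API LAM
#' database; (2) neat-API landscape and `U_API`; (3) per coformer: LAM
#' database, neat landscape, cocrystal search at each requested stoichiometry,
#' ddU (with fusion correction for liquid coformers); (4) ranked, classified
#' report. LAM databases are built at most once per molecule (and reused from
#' `lam_dir` across runs); supplied experimental structures compete with the
#' CSP best under the `"experimental"` energy-source policy.
#'
#' @param api `list(molecule, torsions = , oracle = , experimental = )`;
#'   only `molecule` is required. `experimental`, if given, is a
#'   [crystal_structure()] whose energy competes with the CSP minimum.
#' @param coformers named list of coformer specs with the same fields plus
#'   optional `fusion` ([fusion_data()]).
#' @param config a [search_config()] template; its components are replaced
#'   per composition, everything else (seed, groups, counts, bounds) is
#'   reused.
#' @param params a [potential_params()].
#' @param stoichiometries list of `c(n, m)` pairs to try (default 1:1 only);
#'   the minimum-ddU stoichiometry is reported.
#' @param threshold classification threshold (preset name or kJ/mol).
#' @param lam_dir optional directory for persisting/reusing LAM databases.
#' @param cluster_cfg a [cluster_config()] for duplicate removal.
#' @param lam_spacing torsion-grid spacing in degrees.
#' @param policy energy-source policy, `"csp"` or `"experimental"`.
#' @param fusion_policy `"fusion"` or `"rt"`, see [fusion_correction()].
#' @param progress print stage messages.
#' @return An object of class `ccs_screenreport`.
#' @export
run_screen <- function(api, coformers, config, params,
                       stoichiometries = list(c(1, 1)),
                       threshold = "screening", lam_dir = NULL,
                       cluster_cfg = cluster_config(),
                       lam_spacing = 60,
                       policy = c("csp", "experimental"),
                       fusion_policy = "fusion", progress = FALSE) {
  policy <- match.arg(policy)
  say <- function(...) if (progress) message(...)
  lamdbs <- list()
  get_lam <- function(spec) {
    mol <- spec$molecule
    if (!is.null(lamdbs[[mol$id]])) return(lamdbs[[mol$id]])
    path <- if (!is.null(lam_dir)) file.path(lam_dir, mol$id) else NULL
    if (!is.null(path) && file.exists(file.path(path, "meta.json"))) {
      db <- load_lam(path)
    } else {
      tor <- spec$torsions
      if (is.null(tor)) tor <- integer(0)
      if (length(tor) > 0 && is.null(spec$oracle))
        stop("flexible molecule '", mol$id, "' needs a conformational oracle")
      db <- if (length(tor) > 0)
        build_lam_grid(mol, tor, spec$oracle, spacing = lam_spacing)
      else NULL
      if (!is.null(db) && !is.null(path)) save_lam(db, path)
    }
    lamdbs[[mol$id]] <<- db
    db
  }

  neat_min <- function(spec, label) {
    db <- get_lam(spec)
    dbs <- if (is.null(db)) list() else setNames(list(db), spec$molecule$id)
    cfg <- config
    tor0 <- if (is.null(db)) numeric(0) else rep(0, length(db$torsions))
    cfg$components <- list(list(molecule = spec$molecule, count = 1,
                                torsions = tor0))
    say("  neat search: ", label)
    minima <- global_search(cfg, dbs, params)
    land <- cluster_landscape(minima, cluster_cfg, composition = label)
    exp_ref <- NULL
    if (!is.null(spec$experimental)) {
      en <- total_lattice_energy(spec$experimental, dbs, params)
      exp_ref <- list(structure = spec$experimental, U_total = en$U_total)
    }
    gm <- global_minimum(land, experimental = exp_ref, policy = policy)
    list(U = gm$U_total, source = gm$source, landscape = land)
  }

  api_res <- neat_min(api, api$molecule$id)
  rows <- list(); errors <- list(); landscapes <- list(api = api_res$landscape)
  for (nm in names(coformers)) {
    spec <- coformers[[nm]]
    res <- tryCatch({
      cof_res <- neat_min(spec, nm)
      best <- NULL
      for (st in stoichiometries) {
        n <- st[1]; m <- st[2]
        cfg <- config
        db_api <- get_lam(api); db_cof <- get_lam(spec)
        tor_api <- if (is.null(db_api)) numeric(0) else rep(0, length(db_api$torsions))
        tor_cof <- if (is.null(db_cof)) numeric(0) else rep(0, length(db_cof$torsions))
        cfg$components <- list(
          list(molecule = api$molecule, count = n, torsions = tor_api),
          list(molecule = spec$molecule, count = m, torsions = tor_cof))
        dbs <- Filter(Negate(is.null),
                      setNames(list(db_api, db_cof),
                               c(api$molecule$id, spec$molecule$id)))
        say("  cocrystal search: ", api$molecule$id, "_", n, " ", nm, "_", m)
        minima <- global_search(cfg, dbs, params)
        land <- cluster_landscape(minima, cluster_cfg,
                                  composition = paste0(api$molecule$id, n, nm, m))
        gm <- global_minimum(land)
        dd <- delta_delta_U(gm$U_total, api_res$U, cof_res$U, n = n, m = m,
                            fusion = spec$fusion,
                            hash_cc = params$hash, hash_api = params$hash,
                            hash_c = params$hash,
                            fusion_policy = fusion_policy)
        cand <- list(n = n, m = m, U_cc = gm$U_total, ddU = as.numeric(dd),
                     correction = attr(dd, "correction"), landscape = land)
        if (is.null(best) || cand$ddU < best$ddU) best <- cand
      }
      landscapes[[nm]] <- list(neat = cof_res$landscape, cocrystal = best$landscape)
      data.frame(coformer = nm, n = best$n, m = best$m,
                 U_cc = best$U_cc, U_api = api_res$U, U_c = cof_res$U,
                 correction = best$correction, ddU = best$ddU,
                 api_source = api_res$source, c_source = cof_res$source,
                 observed = isTRUE(spec$observed),
                 stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[nm]] <- conditionMessage(res)
      warning("coformer '", nm, "' failed: ", conditionMessage(res))
    } else {
      rows[[nm]] <- res
    }
  }
  entries <- if (length(rows)) do.call(rbind, rows) else
    data.frame(coformer = character(0), ddU = numeric(0))
  entries <- classify(rank_coformers(entries), threshold)
  thr <- attr(entries, "threshold")
  structure(list(api = api$molecule$id, entries = entries,
                 threshold = thr,
                 stats = if (nrow(entries)) screening_stats(entries, thr) else NULL,
                 errors = errors, landscapes = landscapes,
                 config = list(seed = config$seed,
                               spacegroups = config$spacegroups,
                               n_candidates = config$n_candidates,
                               policy = policy,
                               params_hash = params$hash)),
            class = "ccs_screenreport")
}

#' Screening-only mode from precomputed lattice energies
#'
#' Bypasses the search engine: takes a table of best lattice energies per
#' pair and produces the same ranked, classified report.
#'
#' @param tab data.frame (or CSV path) with columns `coformer`, `U_cc`,
#'   `U_api`, `U_c`, optional `n`, `m`, `T_fus`, `dH_fus`, `observed`.
#' @param threshold preset name or kJ/mol.
#' @param T screening temperature in K for fusion corrections.
#' @param api label for the report.
#' @return A `ccs_screenreport`.
#' @export
screen_from_table <- function(tab, threshold = "screening", T = 300,
                              api = "API") {
  if (is.character(tab)) tab <- read.csv(tab, stringsAsFactors = FALSE)
  if (is.null(tab$n)) tab$n <- 1
  if (is.null(tab$m)) tab$m <- 1
  if (is.null(tab$observed)) tab$observed <- FALSE
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    fus <- NULL
    if (!is.null(tab$T_fus) && is.finite(r$T_fus) && !is.na(r$T_fus))
      fus <- fusion_data(r$T_fus, r$dH_fus, T = T)
    dd <- delta_delta_U(r$U_cc, r$U_api, r$U_c, n = r$n, m = r$m, fusion = fus)
    data.frame(coformer = r$coformer, n = r$n, m = r$m, U_cc = r$U_cc,
               U_api = r$U_api, U_c = r$U_c,
               correction = attr(dd, "correction"), ddU = as.numeric(dd),
               observed = isTRUE(r$observed), stringsAsFactors = FALSE)
  })
  entries <- classify(rank_coformers(do.call(rbind, rows)), threshold)
  thr <- attr(entries, "threshold")
  structure(list(api = api, entries = entries, threshold = thr,
                 stats = screening_stats(entries, thr), errors = list(),
                 config = list(mode = "table")),
            class = "ccs_screenreport")
}

#' @export
print.ccs_screenreport <- function(x, ...) {
  cat("<coformer screen>", x$api, "-", nrow(x$entries), "coformer(s), threshold",
      x$threshold, "kJ/mol\n")
  if (nrow(x$entries)) {
    print(x$entries[, c("rank", "coformer", "n", "m", "ddU", "classification")],
          row.names = FALSE)
    if (!is.null(x$stats))
      cat(sprintf("excluded: %d%%  hits among retained: %s%%\n",
                  x$stats$exclusion_pct,
                  ifelse(is.na(x$stats$hit_pct), "n/a", x$stats$hit_pct)))
  }
  if (length(x$errors))
    cat("failed coformers:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

#' Export a screen report
#'
#' Writes the report as JSON, the entry table as CSV and a rank-vs-ddU CSV
#' suitable for a ranked bar chart.
#'
#' @param report a `ccs_screenreport`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
save_screen_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(api = report$api, threshold = report$threshold,
                            entries = report$entries, stats = report$stats,
                            config = report$config),
                       file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  write.csv(report$entries, file.path(dir, "report.csv"), row.names = FALSE)
  write.csv(report$entries[, c("rank", "coformer", "ddU")],
            file.path(dir, "ranked_ddU.csv"), row.names = FALSE)
  invisible(dir)
}
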