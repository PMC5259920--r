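# Human-readable report bundle (markdown + CSV) over analysis results.
# CSV is the contract; the markdown mirrors the deterministic-results table
# layout, the tornado ordering and the acceptability curve.

fmt_gbp <- function(x) {
  ifelse(is.na(x), "-", paste0("£", formatC(x, format = "f", digits = 0,
                                            big.mark = ",")))
}

md_table <- function(df, digits = 4) {
  fmt <- function(v) {
    if (is.numeric(v)) formatC(v, format = "g", digits = digits) else as.character(v)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

#' Render a markdown + CSV report bundle
#'
#' Writes, for whichever analyses are supplied: the deterministic result
#' table and both incremental comparisons (`base_case.csv`,
#' `base_case.json`), the tornado table sorted by spread (`tornado.csv`),
#' the PSA draws and acceptability curve (`psa_draws.csv`, `ceac.csv`),
#' the duration scenarios (`scenarios.csv`), the auxiliary-default
#' sensitivity table (`auxiliary_sensitivity.csv`), a run log recording
#' parameter provenance and seeds, and `report.md` tying them together.
#'
#' @param dir Output directory (created if needed).
#' @param base A `vte_base_case` (required).
#' @param owsa Optional `vte_owsa`.
#' @param psa Optional `vte_psa`.
#' @param scenarios Optional named list of `vte_incremental` scenario
#'   results.
#' @param aux Optional data.frame from [auxiliary_sensitivity()].
#' @param p Parameter set used (for the provenance log).
#' @return Named list of written paths, invisibly.
#' @export
render_report <- function(dir, base, owsa = NULL, psa = NULL,
                          scenarios = NULL, aux = NULL,
                          p = default_parameters()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  md <- c("# Lifetime cost-effectiveness of apixaban versus LMWH/VKA for VTE",
          "")

  # base case
  paths$base_case_csv <- file.path(dir, "base_case.csv")
  utils::write.csv(base$table, paths$base_case_csv, row.names = FALSE)
  inc_df <- do.call(rbind, lapply(list(base$vs_6m, base$vs_18m), function(x) {
    data.frame(intervention = x$intervention, comparator = x$comparator,
               d_cost = x$d_cost, d_qaly = x$d_qaly, d_ly = x$d_ly,
               icer = x$icer, dominance = x$dominance)
  }))
  paths$base_case_json <- file.path(dir, "base_case.json")
  jsonlite::write_json(list(arms = base$table, incremental = inc_df),
                       paths$base_case_json, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")
  md <- c(md, "## Deterministic results", "", md_table(base$table, 6), "",
          "## Incremental comparisons", "", md_table(inc_df, 5), "")

  if (!is.null(owsa)) {
    paths$tornado_csv <- file.path(dir, "tornado.csv")
    utils::write.csv(owsa$table, paths$tornado_csv, row.names = FALSE)
    md <- c(md, sprintf("## One-way sensitivity (vs %s, base ICER %s)",
                        owsa$comparison, fmt_gbp(owsa$base_icer)), "",
            md_table(utils::head(owsa$table, 15), 5), "")
  }
  if (!is.null(psa)) {
    paths$psa_draws_csv <- file.path(dir, "psa_draws.csv")
    utils::write.csv(psa$draws, paths$psa_draws_csv, row.names = FALSE)
    paths$ceac_csv <- file.path(dir, "ceac.csv")
    utils::write.csv(psa$ceac, paths$ceac_csv, row.names = FALSE)
    md <- c(md, "## Probabilistic sensitivity analysis", "",
            sprintf("%d draws (seed %d): probability %s is most cost-effective at %s/QALY = **%.1f%%**",
                    psa$n_draws, psa$seed, psa$arm_names[1],
                    fmt_gbp(psa$wtp), 100 * psa$p_ce_at_wtp), "")
  }
  if (!is.null(scenarios)) {
    sc <- do.call(rbind, lapply(names(scenarios), function(nm) {
      x <- scenarios[[nm]]
      data.frame(scenario = nm, intervention = x$intervention,
                 comparator = x$comparator, d_cost = x$d_cost,
                 d_qaly = x$d_qaly, icer = x$icer, dominance = x$dominance)
    }))
    paths$scenarios_csv <- file.path(dir, "scenarios.csv")
    utils::write.csv(sc, paths$scenarios_csv, row.names = FALSE)
    md <- c(md, "## Treatment-duration scenarios", "", md_table(sc, 5), "")
  }
  if (!is.null(aux)) {
    paths$aux_csv <- file.path(dir, "auxiliary_sensitivity.csv")
    utils::write.csv(aux, paths$aux_csv, row.names = FALSE)
    md <- c(md, "## Sensitivity to non-published auxiliary defaults", "",
            md_table(aux, 5), "")
  }

  # run log: provenance of every input, seed, version
  tab <- parameter_table(p)
  paths$run_log <- file.path(dir, "run_log.txt")
  log <- c(sprintf("apixcea %s", as.character(utils::packageVersion("apixcea"))),
           sprintf("assumption-sourced inputs (%d):",
                   sum(tab$source == "assumption")),
           sprintf("  %s = %g", tab$name[tab$source == "assumption"],
                   tab$value[tab$source == "assumption"]),
           if (!is.null(psa)) sprintf("PSA seed: %d", psa$seed))
  writeLines(log, paths$run_log)
  md <- c(md,
          "All numbers above are reproducible from the parameter file, the",
          "life table and the seed recorded in `run_log.txt`.", "")

  paths$report_md <- file.path(dir, "report.md")
  writeLines(md, paths$report_md)
  invisible(paths)
}

#' Command-line entry point
#'
#' Thin wrapper used by `inst/cli/apixcea.R`.  Subcommands: `fixture`
#' (write the packaged parameter fixture), `base`, `owsa`, `psa`,
#' `scenario`.  Options: `--params`, `--life-table` (path or "synthetic"),
#' `--out`, `--comparison`, `--draws`, `--seed`, `--apixaban-months`,
#' `--comparator-months`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 success), invisibly.
#' @export
apixcea_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: apixcea.R <fixture|base|owsa|psa|scenario> [--params FILE]",
    "[--life-table FILE|synthetic] [--out DIR] [--comparison vka6|vka18]",
    "[--draws N] [--seed N] [--apixaban-months N|Inf]",
    "[--comparator-months N|Inf]")
  opt <- list(params = NULL, `life-table` = "synthetic", out = "apixcea_out",
              comparison = "vka6", draws = "200", seed = "1",
              `apixaban-months` = "Inf", `comparator-months` = "6")
  if (length(args) < 1) { message(usage); return(invisible(2)) }
  cmd <- args[1]; args <- args[-1]
  i <- 1
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!startsWith(args[i], "--") || !key %in% names(opt) ||
        i == length(args)) {
      message("bad flag: ", args[i], "\n", usage)
      return(invisible(2))
    }
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  status <- tryCatch({
    if (cmd == "fixture") {
      paths <- packaged_fixture(opt$out)
      message("fixture written to ", opt$out)
      return(invisible(0))
    }
    p <- if (is.null(opt$params)) default_parameters()
         else load_parameters(opt$params)
    lt <- if (identical(opt$`life-table`, "synthetic")) generate_life_table()
          else read_life_table(opt$`life-table`)
    seed <- as.integer(opt$seed)
    switch(cmd,
      base = {
        bc <- run_base_case(p, lt)
        aux <- auxiliary_sensitivity(p, lt)
        render_report(opt$out, bc, aux = aux, p = p)
      },
      owsa = {
        bc <- run_base_case(p, lt)
        ow <- run_owsa(p, lt, comparison = opt$comparison)
        render_report(opt$out, bc, owsa = ow, p = p)
      },
      psa = {
        bc <- run_base_case(p, lt)
        ps <- run_psa(p, lt, n_draws = as.integer(opt$draws), seed = seed)
        render_report(opt$out, bc, psa = ps, p = p)
      },
      scenario = {
        bc <- run_base_case(p, lt)
        am <- as.numeric(opt$`apixaban-months`)
        cm <- as.numeric(opt$`comparator-months`)
        sc <- list(scenario = run_scenario_durations(p, lt, am, cm))
        render_report(opt$out, bc, scenarios = sc, p = p)
      },
      { message("unknown subcommand: ", cmd, "\n", usage)
        return(invisible(2)) })
    message("report written to ", opt$out)
    0
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1
  })
  invisible(status)
}
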