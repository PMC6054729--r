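#' Analysis configuration
#'
#' Bundles every tunable of the full pipeline: the permutation scheme, the
#' combining function, the familywise level, the adjusted-p cap and the
#' rendering precision.
#'
#' @param B Number of permutations; default 10000.
#' @param seed Integer seed for the permutation stream.
#' @param method Combining function: `"fisher"` (default), `"liptak"` or
#'   `"tippett"`.
#' @param alpha Familywise level in `(0, 1)`; default 0.05.
#' @param cap Adjusted p-value cap; 1 by default, 0.9999 for compatibility
#'   with permutation software that saturates at the largest expressible raw
#'   p-value.
#' @param report_precision Decimal places in rendered reports; default 4.
#' @param exact_threshold,mode,tie_tol Passed to [perm_scheme()].
#' @param studentize Use the pooled-variance t statistic for numeric
#'   variables; default `FALSE` (raw absolute mean difference).
#' @return An object of class `"analysis_config"`.
#' @export
analysis_config <- function(B = 10000L, seed = 1L,
                            method = c("fisher", "liptak", "tippett"),
                            alpha = 0.05, cap = 1, report_precision = 4L,
                            exact_threshold = 20000L,
                            mode = c("auto", "random", "exact"),
                            tie_tol = 1e-12, studentize = FALSE) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0,1)", call. = FALSE)
  if (report_precision < 1) stop("'report_precision' must be >= 1",
                                 call. = FALSE)
  structure(list(scheme = perm_scheme(B = B, seed = seed,
                                      exact_threshold = exact_threshold,
                                      mode = mode, tie_tol = tie_tol),
                 method = method, alpha = alpha, cap = cap,
                 report_precision = as.integer(report_precision),
                 studentize = studentize),
            class = "analysis_config")
}

#' Run the full two-group comparison pipeline
#'
#' Executes, on one shared permutation stream: per-variable complete-case
#' extraction and summaries; all `K` partial permutation tests (every
#' variable sees the same unit-level reassignments, restricted to its own
#' complete cases, which preserves the inter-variable dependence the NPC
#' combination relies on); the NPC global test; and the Bonferroni-Holm
#' step-down over the raw partial p-values. Re-running with identical inputs
#' and configuration is bit-identical.
#'
#' @param table A [cohort_table()].
#' @param specs Variable specs; defaults to those stored in the table.
#' @param config An [analysis_config()].
#' @return Object of class `"analysis_report"`: list with `summaries`
#'   (per-variable group summaries), `partials` (list of [partial_test()]
#'   results), `npc` ([npc_global_test()] result), `holm` (the
#'   [holm_table()] data frame) and `metadata`.
#' @export
run_analysis <- function(table, specs = NULL, config = analysis_config()) {
  stopifnot(inherits(table, "cohort_table"),
            inherits(config, "analysis_config"))
  if (is.null(specs)) specs <- table$specs
  specs <- check_specs(specs)
  if (!length(specs)) stop("at least one variable required", call. = FALSE)

  A <- generate_assignments(table$n1, table$n2, config$scheme)
  A <- align_assignments(A, table$groups)
  A1 <- (A == 1L) * 1

  summaries <- list()
  partials <- vector("list", length(specs))
  names(partials) <- names(specs)
  for (nm in names(specs)) {
    cc <- extract_complete(table, nm)
    summaries[[nm]] <- summarize_variable(cc$x1, cc$x2, specs[[nm]])
    partials[[nm]] <- partial_test(table, nm, specs[[nm]],
                                   scheme = config$scheme, assignments = A,
                                   studentize = config$studentize, A1 = A1)
  }
  npc <- npc_global_test(partials, method = config$method,
                         tie_tol = config$scheme$tie_tol)
  holm <- holm_table(npc$partial_raw_p, alpha = config$alpha,
                     cap = config$cap)
  res <- list(summaries = summaries, partials = partials, npc = npc,
              holm = holm,
              metadata = list(seed = config$scheme$seed,
                              B = nrow(A), method = config$method,
                              alpha = config$alpha, cap = config$cap,
                              mode = attr(A, "mode"),
                              group_labels = table$group_labels,
                              n1 = table$n1, n2 = table$n2,
                              complete_cases = vapply(
                                partials, function(p) p$n1 + p$n2,
                                integer(1)),
                              version = as.character(
                                utils::packageVersion("npcholm"))))
  class(res) <- "analysis_report"
  res
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(render_report(x, style = "summary"), sep = "\n")
  invisible(x)
}

# Format a p-value at `digits` decimals; values at the 1/B floor in the
# combined line are rendered below printable resolution.
format_pvalue <- function(p, digits = 4, B = NULL, floor_special = FALSE) {
  if (floor_special && !is.null(B) && p <= 1 / B + 1e-15)
    return(sprintf(paste0("%.", digits, "f (< %.0e)"), 0, 1 / B))
  sprintf(paste0("%.", digits, "f"), p)
}

#' Render an analysis report
#'
#' Three styles: `"summary"` prints per-variable group summaries (mean and SD
#' for numeric variables, first-level percentages for categorical ones) with
#' raw p-values and the combined p-value line; `"holm"` prints raw p-value,
#' ascending rank and adjusted p-value with a significance marker; and
#' `"machine"` emits a lossless tab-separated dump (17 significant digits)
#' that [parse_machine_report()] reads back exactly.
#'
#' @param report An [run_analysis()] result.
#' @param style `"summary"`, `"holm"` or `"machine"`.
#' @param digits Decimal places for the human-readable styles; defaults to 4.
#' @return Character vector of lines.
#' @export
render_report <- function(report, style = c("summary", "holm", "machine"),
                          digits = 4) {
  stopifnot(inherits(report, "analysis_report"))
  style <- match.arg(style)
  md <- report$metadata
  fmt <- function(p) format_pvalue(p, digits)

  if (style == "summary") {
    lines <- c(sprintf("Two-group comparison: %s (n=%d) vs %s (n=%d)",
                       md$group_labels[1], md$n1, md$group_labels[2], md$n2),
               sprintf("%-32s %18s %18s %8s", "Variable",
                       md$group_labels[1], md$group_labels[2], "p-value"))
    for (nm in names(report$summaries)) {
      s <- report$summaries[[nm]]
      cell <- function(i) {
        if (s$kind == "numeric")
          sprintf("%.2f +/- %.2f", s[[paste0("mean", i)]],
                  s[[paste0("sd", i)]])
        else {
          pc <- s[[paste0("pct", i)]]
          paste(sprintf("%.1f", pc[seq_len(min(2, length(pc)))]),
                collapse = " / ")
        }
      }
      lines <- c(lines, sprintf("%-32s %18s %18s %8s", nm, cell(1), cell(2),
                                fmt(report$partials[[nm]]$raw_p)))
    }
    c(lines, sprintf("%-32s %46s",
                     sprintf("COMBINED p-value (%s)", md$method),
                     format_pvalue(report$npc$combined_p, digits, md$B,
                                   floor_special = TRUE)))
  } else if (style == "holm") {
    h <- report$holm
    lines <- sprintf("%-32s %8s %4s %8s %s", "Variable", "raw p", "i",
                     "adj p", "")
    for (r in seq_len(nrow(h))) {
      lines <- c(lines, sprintf("%-32s %8s %4d %8s %s",
                                h$variable[r], fmt(h$raw_p[r]), h$rank_i[r],
                                fmt(h$adj_p[r]),
                                if (h$significant[r]) "*" else ""))
    }
    c(lines, sprintf("* significant after Holm step-down at alpha = %g",
                     md$alpha))
  } else {
    num <- function(x) sprintf("%.17g", x)
    lines <- c("section\tvariable\tfield\tvalue",
               sprintf("meta\t.\tseed\t%s", num(md$seed)),
               sprintf("meta\t.\tB\t%s", num(md$B)),
               sprintf("meta\t.\tmethod\t%s", md$method),
               sprintf("meta\t.\talpha\t%s", num(md$alpha)),
               sprintf("meta\t.\tcap\t%s", num(md$cap)),
               sprintf("meta\t.\tn1\t%s", num(md$n1)),
               sprintf("meta\t.\tn2\t%s", num(md$n2)),
               sprintf("meta\t.\tgroup1\t%s", md$group_labels[1]),
               sprintf("meta\t.\tgroup2\t%s", md$group_labels[2]),
               sprintf("meta\t.\tversion\t%s", md$version))
    h <- report$holm
    for (r in seq_len(nrow(h))) {
      nm <- h$variable[r]
      p <- report$partials[[nm]]
      lines <- c(lines,
                 sprintf("partial\t%s\tt_obs\t%s", nm, num(p$t_obs)),
                 sprintf("partial\t%s\traw_p\t%s", nm, num(h$raw_p[r])),
                 sprintf("partial\t%s\trank_i\t%s", nm, num(h$rank_i[r])),
                 sprintf("partial\t%s\tadj_p\t%s", nm, num(h$adj_p[r])),
                 sprintf("partial\t%s\tsignificant\t%s", nm,
                         num(as.integer(h$significant[r]))),
                 sprintf("partial\t%s\tn_complete\t%s", nm,
                         num(md$complete_cases[[nm]])))
    }
    c(lines,
      sprintf("npc\t.\tpsi_obs\t%s", num(report$npc$psi_obs)),
      sprintf("npc\t.\tcombined_p\t%s", num(report$npc$combined_p)))
  }
}

#' Parse a machine-style report back into numbers
#'
#' @param lines Character vector produced by
#'   `render_report(style = "machine")`.
#' @return A `data.frame` with columns `section`, `variable`, `field`,
#'   `value` (character) and `value_num` (numeric where parseable).
#' @export
parse_machine_report <- function(lines) {
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  df$value_num <- suppressWarnings(as.numeric(df$value))
  df
}

#' Multiplicity stage on a bare p-value vector
#'
#' The recompute-from-p-values entry point: runs only the Bonferroni-Holm
#' step-down on raw p-values supplied directly, with no cohort or
#' permutations. The published adjusted values of the emulated study are a
#' pure function of its printed raw values, so
#' `adjust_pvalues(ibd_raw_pvalues(), cap = 0.9999)` reproduces them.
#'
#' @param raw_ps Numeric vector (optionally named) of raw p-values.
#' @inheritParams holm_table
#' @return The [holm_table()] data frame.
#' @export
adjust_pvalues <- function(raw_ps, alpha = 0.05, cap = 1) {
  holm_table(raw_ps, alpha = alpha, cap = cap)
}
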