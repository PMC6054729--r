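# Small deterministic fixtures built in code.

small_specs <- function() {
  list(variable_spec("age", "numeric"),
       variable_spec("smoker", "categorical", levels = c("yes", "no")))
}

# A tiny mixed cohort with optional missing cells.
small_cohort <- function(missing_cells = NULL) {
  data <- data.frame(
    age = c(31, 45, 52, 38, 60, 41, 55, 47),
    smoker = c("yes", "no", "yes", "yes", "no", "no", "yes", "no"),
    stringsAsFactors = FALSE)
  if (!is.null(missing_cells))
    for (mc in missing_cells) data[mc[[1]], mc[[2]]] <- NA
  cohort_table(c(1, 1, 1, 1, 2, 2, 2, 2), data, small_specs())
}

# Random small cohort for oracle comparisons: n1 + n2 <= 10, K <= 3,
# mixed kinds, categorical columns guaranteed non-degenerate.
random_small_cohort <- function() {
  n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
  n <- n1 + n2
  K <- sample(1:3, 1)
  kinds <- sample(c("numeric", "categorical"), K, replace = TRUE)
  specs <- list(); data <- list()
  for (k in seq_len(K)) {
    nm <- paste0("v", k)
    if (kinds[k] == "numeric") {
      specs[[k]] <- variable_spec(nm, "numeric")
      data[[nm]] <- round(rnorm(n), 3)
    } else {
      specs[[k]] <- variable_spec(nm, "categorical", levels = c("a", "b"))
      repeat {
        col <- sample(c("a", "b"), n, replace = TRUE)
        if (length(unique(col)) == 2) break
      }
      data[[nm]] <- col
    }
  }
  cohort_table(c(rep(1, n1), rep(2, n2)),
               as.data.frame(data, stringsAsFactors = FALSE), specs)
}

# Write a cohort CSV from raw text lines.
write_csv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# First `k` variables of the published model at reduced size, under the
# exact global null: used for size simulations.
null_submodel <- function(k = 10, n1 = 60, n2 = 100) {
  m <- default_model()
  null_model(cohort_model(m$variables[seq_len(k), ], n1 = n1, n2 = n2))
}
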