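# Classed conditions: schema violations (malformed/incomplete inputs) vs
# statistical precondition failures (well-formed data the method cannot run on).

stop_schema <- function(msg, ...) {
  abort(msg, class = "ecsig_schema_error", ...)
}

stop_stat <- function(msg, ...) {
  abort(msg, class = "ecsig_stat_error", ...)
}

stop_config <- function(msg, ...) {
  abort(msg, class = "ecsig_config_error", ...)
}

check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_schema(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (if (open_lower) x > lower else x >= lower) &&
    (if (open_upper) x < upper else x <= upper)
  if (!ok) {
    stop_config(sprintf(
      "`%s` must be a single number in %s%s, %s%s",
      name,
      if (open_lower) "(" else "[", format(lower),
      format(upper), if (open_upper) ")" else "]"
    ))
  }
  invisible(x)
}

# Coerce the various accepted sample-annotation shapes (tibble with
# sample/group columns, named vector, bare factor aligned with colnames)
# into a factor of group labels ordered like the count-matrix columns.
sample_group_factor <- function(counts, sample_groups) {
  samples <- colnames(counts)
  if (is.data.frame(sample_groups)) {
    check_columns(sample_groups, c("sample", "group"), "sample annotation")
    idx <- match(samples, sample_groups$sample)
    if (anyNA(idx)) {
      stop_schema(sprintf(
        "sample annotation lacks entries for: %s",
        paste(samples[is.na(idx)], collapse = ", ")
      ))
    }
    grp <- sample_groups$group[idx]
  } else if (!is.null(names(sample_groups))) {
    idx <- match(samples, names(sample_groups))
    if (anyNA(idx)) {
      stop_schema("named `sample_groups` does not cover all count columns")
    }
    grp <- unname(sample_groups[idx])
  } else {
    if (length(sample_groups) != length(samples)) {
      stop_schema("`sample_groups` length does not match number of samples")
    }
    grp <- sample_groups
  }
  factor(as.character(grp), levels = unique(as.character(grp)))
}
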