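# Lempel-Ziv 76 phrase counting, normalized complexity estimates, the
# brute-force oracle, and the calibration harness for the normalization.

# Map an arbitrary finite-alphabet sequence to a single string of one
# character per symbol, so substring checks run at C speed.
seq_to_string <- function(symbols) {
  alpha <- unique(symbols)
  if (length(alpha) > 60000L) stop("alphabet too large", call. = FALSE)
  intToUtf8(match(symbols, alpha) + 64L, multiple = FALSE)
}

#' Lempel-Ziv 76 phrase count
#'
#' Number of phrases in the exhaustive-history parsing of a sequence: the
#' parser scans left to right and closes a phrase each time it encounters a
#' substring of consecutive symbols not seen anywhere in the preceding
#' text (self-overlap allowed, as in the classical copy-and-insert
#' formulation). The final, possibly still-copyable phrase counts as a
#' phrase (the standard end-of-string convention; published variants
#' differ, see the package vignette).
#'
#' @param x A `symbol_sequence`, or a character vector of symbols.
#' @return Positive integer phrase count.
#' @examples
#' lz76_phrase_count(c("0", "1"))              # 2
#' lz76_phrase_count(strsplit("010101", "")[[1]])  # 3: 0 | 1 | 0101
#' @export
lz76_phrase_count <- function(x) {
  symbols <- if (inherits(x, "symbol_sequence")) x$symbols else as.character(x)
  n <- length(symbols)
  if (n == 0L) stop("empty sequence", call. = FALSE)
  s <- seq_to_string(symbols)
  c_count <- 1L
  i <- 2L                         # start of the current phrase (1-based)
  while (i <= n) {
    k <- 1L
    repeat {
      q <- substr(s, i, i + k - 1L)
      prefix <- substr(s, 1L, i + k - 2L)
      found <- grepl(q, prefix, fixed = TRUE)
      if (found && i + k <= n) { k <- k + 1L; next }
      c_count <- c_count + 1L
      i <- if (found) n + 1L else i + k
      break
    }
  }
  c_count
}

#' Brute-force phrase-count oracle
#'
#' Independent verification oracle for [lz76_phrase_count()]: explicit
#' history enumeration with naive substring scanning. At every extension
#' step the complete set of substrings of the preceding text is enumerated
#' and membership is tested against it. Capped at length 12.
#'
#' @param x A `symbol_sequence` or character vector.
#' @return Positive integer; equals `lz76_phrase_count(x)` by construction
#'   of the parsing, which the test suite verifies exhaustively.
#' @export
brute_force_phrase_oracle <- function(x) {
  symbols <- if (inherits(x, "symbol_sequence")) x$symbols else as.character(x)
  n <- length(symbols)
  if (n == 0L) stop("empty sequence", call. = FALSE)
  if (n > 12L) stop("oracle capped at length 12", call. = FALSE)
  s <- seq_to_string(symbols)
  all_substrings <- function(upto) {
    if (upto < 1L) return(character(0))
    a <- rep.int(seq_len(upto), rev(seq_len(upto)))
    b <- unlist(lapply(seq_len(upto), function(i) i:upto), use.names = FALSE)
    substring(s, a, b)
  }
  history <- character(0)
  pos <- 1L
  while (pos <= n) {
    len <- 1L
    repeat {
      word <- substring(s, pos, pos + len - 1L)
      seen <- word %in% all_substrings(pos + len - 2L)
      if (seen && pos + len <= n) { len <- len + 1L; next }
      history <- c(history, word)
      pos <- pos + if (seen) n else len   # end-of-string phrase closes parse
      break
    }
  }
  length(history)
}

#' Normalization schemes
#'
#' The finite family of normalizations over which the calibration searches.
#' The candidate formulas are `c * log(n) / n` and its algebraically
#' identical ratio form `c / (n / log n)`, with the logarithm taken to base
#' 2 or to the alphabet size, plus the raw phrase count. The shipped
#' default, selected by [calibrate_scheme()], is `ks_log2`:
#' `c * log2(n) / n`.
#'
#' @param id Scheme identifier; see `normalization_schemes()` for the grid.
#' @return `complexity_scheme()`: a scheme object; `normalization_schemes()`:
#'   character vector of ids in fixed (tie-break) order.
#' @export
complexity_scheme <- function(id = "ks_log2") {
  grid <- list(
    ks_log2    = list(formula = "c*log(n)/n",   log_base = "2"),
    ratio_log2 = list(formula = "c/(n/log(n))", log_base = "2"),
    ks_logA    = list(formula = "c*log(n)/n",   log_base = "alpha"),
    ratio_logA = list(formula = "c/(n/log(n))", log_base = "alpha"),
    raw_c      = list(formula = "raw",          log_base = "2"))
  if (!id %in% names(grid)) stop("unknown scheme id: ", id, call. = FALSE)
  structure(c(list(id = id), grid[[id]]), class = "complexity_scheme")
}

#' @rdname complexity_scheme
#' @export
normalization_schemes <- function() {
  c("ks_log2", "ratio_log2", "ks_logA", "ratio_logA", "raw_c")
}

#' Normalized Lempel-Ziv complexity
#'
#' Applies a normalization scheme to the LZ76 phrase count of a sequence.
#' For the default scheme the value is `c * log2(n) / n`, the
#' Kaspar-Schuster normalization by the asymptotic phrase count of a random
#' sequence; on the short sequences typical of derivational encodings it
#' takes values roughly between 1 and 2.5 and is reported as printed, not
#' capped at 1.
#'
#' @param x A `symbol_sequence` or character vector.
#' @param scheme A `complexity_scheme` or scheme id.
#' @param binarize Binary recoding applied first (see
#'   [binarize_sequence()]); `"none"` by default.
#' @param warn_short Warn when the (possibly recoded) sequence is shorter
#'   than 10 symbols; Lempel-Ziv estimates are unstable on very short
#'   sequences and values should be compared only within a fixed encoding
#'   convention.
#' @return A `complexity_result`: `phrase_count`, `length`,
#'   `alphabet_size`, `normalized`, `scheme`.
#' @export
normalized_complexity <- function(x, scheme = complexity_scheme("ks_log2"),
                                  binarize = "none", warn_short = TRUE) {
  if (is.character(scheme)) scheme <- complexity_scheme(scheme)
  if (!inherits(x, "symbol_sequence")) x <- symbol_sequence(x)
  if (!identical(binarize, "none")) x <- binarize_sequence(x, binarize)
  n <- length(x$symbols)
  alpha <- length(x$alphabet)
  if (warn_short && n < 10L)
    warning(sprintf(paste0("sequence length %d < 10: Lempel-Ziv complexity ",
                           "estimates are unstable on very short sequences"), n),
            call. = FALSE)
  cc <- lz76_phrase_count(x)
  lg <- switch(scheme$log_base,
               "2" = log2(n),
               "alpha" = if (alpha > 1L) log(n, base = alpha) else log2(n))
  value <- switch(scheme$formula,
                  "c*log(n)/n" = cc * lg / n,
                  "c/(n/log(n))" = cc / (n / lg),
                  "raw" = as.numeric(cc))
  structure(list(phrase_count = cc, length = n, alphabet_size = alpha,
                 normalized = value, scheme = scheme$id),
            class = "complexity_result")
}

#' @export
print.complexity_result <- function(x, ...) {
  cat(sprintf("<complexity: C=%.4f (c=%d, n=%d, alpha=%d, scheme=%s)>\n",
              x$normalized, x$phrase_count, x$length, x$alphabet_size,
              x$scheme))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Calibration
## ---------------------------------------------------------------------------

calibration_config_grid <- function(mode) {
  bins <- c("none", "fixed", "fixed1", "minwidth", "minwidth1")
  grid <- switch(mode,
    node_terminal = expand.grid(symbol_policy = "per_distinct_label",
                                copy_policy = "same_symbol_as_antecedent",
                                step_symbols = "nodes",
                                binarize = bins, stringsAsFactors = FALSE),
    search_path = expand.grid(symbol_policy = c("per_distinct_label",
                                                "per_category"),
                              copy_policy = "same_symbol_as_antecedent",
                              step_symbols = c("transitions", "nodes"),
                              binarize = c("none", "fixed", "minwidth"),
                              stringsAsFactors = FALSE),
    movement_path = expand.grid(symbol_policy = c("per_distinct_label",
                                                  "per_category"),
                                copy_policy = "same_symbol_as_antecedent",
                                step_symbols = "nodes",
                                binarize = c("none", "fixed", "minwidth"),
                                stringsAsFactors = FALSE),
    label_sequence = expand.grid(symbol_policy = "per_category",
                                 copy_policy = c("same_symbol_as_antecedent",
                                                 "invisible"),
                                 step_symbols = "nodes",
                                 binarize = c("none", "fixed", "minwidth"),
                                 stringsAsFactors = FALSE))
  grid
}

config_from_row <- function(mode, row) {
  encoding_config(mode,
                  symbol_policy = row$symbol_policy,
                  copy_policy = row$copy_policy,
                  step_symbols = row$step_symbols,
                  binarize = row$binarize)
}

#' Calibrate the normalization scheme and encoder configurations
#'
#' The reference implementation behind the published complexity values for
#' short derivational encodings is not fully specified, so the package
#' pins its defaults by grid search: for every normalization scheme in
#' [normalization_schemes()] and every per-mode encoder configuration in a
#' documented finite family, the four contrast pairs are re-encoded from
#' the fixture structures and scored, and the combination minimizing the
#' total absolute residual against the printed target values is selected.
#' Configurations that fail to reproduce a grammatical-below-ungrammatical
#' ordering are always ranked below those that reproduce it; exact ties are
#' broken by fixed grid order.
#'
#' @param pairs Calibration pairs as produced by [tcc_printed_targets()]:
#'   for each encoder mode, the two fixture-derived inputs and their two
#'   printed target values, grammatical member first.
#' @return A `tcc_calibration`: `scheme` (winning scheme id), `configs`
#'   (winning `encoding_config` per mode), `residuals` (per-pair table of
#'   fitted values, targets, residuals and ordering outcomes), and
#'   `total_residual`. `all_exact` is `TRUE` only if every printed value is
#'   matched to two decimals.
#' @export
calibrate_scheme <- function(pairs = tcc_printed_targets()) {
  if (!length(pairs)) stop("empty calibration grid", call. = FALSE)
  best <- NULL
  for (sid in normalization_schemes()) {
    chosen <- list(); total <- 0; n_bad_order <- 0L
    for (pair in pairs) {
      grid <- calibration_config_grid(pair$mode)
      pbest <- NULL
      for (k in seq_len(nrow(grid))) {
        cfg <- config_from_row(pair$mode, grid[k, , drop = FALSE])
        vals <- vapply(pair$encode(cfg), function(s)
          normalized_complexity(s, sid, binarize = cfg$binarize,
                                warn_short = FALSE)$normalized, 0)
        res <- sum(abs(vals - pair$targets))
        order_ok <- vals[1L] < vals[2L]       # grammatical member first
        key <- c(as.integer(!order_ok), res)
        if (is.null(pbest) || key[1L] < pbest$key[1L] ||
            (key[1L] == pbest$key[1L] && key[2L] < pbest$key[2L] - 1e-12)) {
          pbest <- list(key = key, config = cfg, values = vals,
                        order_ok = order_ok, residual = res)
        }
      }
      chosen[[pair$mode]] <- pbest
      total <- total + pbest$residual
      n_bad_order <- n_bad_order + as.integer(!pbest$order_ok)
    }
    key <- c(n_bad_order, total)
    if (is.null(best) || key[1L] < best$key[1L] ||
        (key[1L] == best$key[1L] && key[2L] < best$key[2L] - 1e-12)) {
      best <- list(key = key, scheme = sid, chosen = chosen, total = total)
    }
  }
  rows <- do.call(rbind, lapply(names(best$chosen), function(m) {
    ch <- best$chosen[[m]]
    pair <- pairs[[which(vapply(pairs, function(p) p$mode, "") == m)]]
    data.frame(mode = m, member = pair$labels,
               value = ch$values, target = pair$targets,
               residual = ch$values - pair$targets,
               ordering_ok = ch$order_ok,
               binarize = ch$config$binarize,
               symbol_policy = ch$config$symbol_policy,
               stringsAsFactors = FALSE)
  }))
  structure(list(scheme = best$scheme,
                 configs = lapply(best$chosen, `[[`, "config"),
                 residuals = rows,
                 total_residual = best$total,
                 all_exact = all(abs(round(rows$value, 2) - rows$target) < 1e-9)),
            class = "tcc_calibration")
}

#' @export
print.tcc_calibration <- function(x, ...) {
  cat("Calibration winner: scheme", x$scheme,
      sprintf("(total |residual| = %.4f, all orderings %s)\n",
              x$total_residual,
              if (all(x$residuals$ordering_ok)) "reproduced" else "NOT reproduced"))
  print(x$residuals, row.names = FALSE, digits = 4)
  if (!x$all_exact)
    cat("Printed values not all matched to two decimals;",
        "the ordering contrasts are the validated surface.\n")
  invisible(x)
}
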