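# Internal helpers shared across modules.

#' Signal a classed immunoscape error
#'
#' All user-facing errors in the package carry a condition class so callers
#' (and the test suite) can distinguish schema problems from numeric
#' degeneracies without parsing messages.
#'
#' @param class character scalar, specific condition class.
#' @param msg sprintf-style message.
#' @param ... values interpolated into `msg`.
#' @noRd
iscape_error <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "immunoscape_error")))
}

iscape_warn <- function(msg, ...) {
  warning(sprintf(msg, ...), call. = FALSE)
}

#' Derive a child RNG seed from a base seed and an integer offset
#'
#' Keeps derived seeds within the 32-bit integer range so they are valid
#' arguments to `set.seed()` on every platform.
#' @noRd
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(offset)) %% 2147483647L)
}

#' Row means / sds that tolerate missing values
#' @noRd
row_sds <- function(m) {
  n <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  ss <- rowSums((m - mu)^2, na.rm = TRUE)
  out <- sqrt(ss / pmax(n - 1, 1))
  out[n < 2] <- NA_real_
  out
}

#' z-scale rows of a matrix; zero-variance rows become all-zero
#'
#' Returns the scaled matrix with the centers and scales used attached as
#' attributes, so module scoring can record its scaling.
#' @noRd
z_scale_rows <- function(m) {
  ctr <- rowMeans(m)
  scl <- row_sds(m)
  scl[is.na(scl) | scl == 0] <- Inf  # zero-variance rows contribute 0
  out <- (m - ctr) / scl
  attr(out, "center") <- ctr
  attr(out, "scale") <- ifelse(is.infinite(scl), 0, scl)
  out
}

#' Deterministic text serialization of a numeric matrix
#'
#' Uses 15 significant digits so re-runs with identical inputs produce
#' byte-identical artifacts.
#' @noRd
write_tsv_matrix <- function(m, path, id_col = "id") {
  cols <- c(list(rownames(m)),
            lapply(seq_len(ncol(m)), function(j) {
              format(m[, j], digits = 15, trim = TRUE, scientific = NA)
            }))
  names(cols) <- c(id_col, colnames(m))
  utils::write.table(as.data.frame(cols, check.names = FALSE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
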