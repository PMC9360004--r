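#' @keywords internal
"_PACKAGE"

#' @import dplyr
#' @import tibble
#' @importFrom tidyr pivot_longer pivot_wider crossing
#' @importFrom purrr map map_dfr map2 imap_dfr
#' @importFrom rlang abort warn .data :=
#' @importFrom stats rnbinom rlnorm rnorm runif setNames phyper wilcox.test
#'   p.adjust median
#' @importFrom utils head modifyList packageVersion
NULL

# Abort with a consistent class so callers can condition on package errors.
stop_tl <- function(msg, ...) {
  rlang::abort(message = sprintf(msg, ...), class = "translatome_error")
}

warn_tl <- function(msg, ...) {
  rlang::warn(message = sprintf(msg, ...), class = "translatome_warning")
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_tl("%s is missing required column(s): %s", what,
            paste(missing, collapse = ", "))
  }
  invisible(df)
}

assert_finite <- function(x, what) {
  if (any(!is.finite(x))) {
    stop_tl("non-finite value in %s", what)
  }
  invisible(x)
}

#' Derive an independent child seed from a master seed and a text tag
#'
#' All stochastic generators in the package draw their randomness from a
#' single integer seed. Child streams for the different generator stages are
#' split off deterministically by hashing the stage tag together with the
#' master seed, so stages are mutually independent but the whole simulation
#' is reproducible from one number.
#'
#' @param seed Master integer seed.
#' @param tag Character tag naming the consumer stream.
#' @return An integer in `[0, 2^31 - 2]` suitable for `set.seed()`.
#' @examples
#' split_seed(1L, "counts") != split_seed(1L, "footprints")
#' @export
split_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(tag))
  # 32-bit multiplicative hash carried out in doubles (exact below 2^53)
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(tag)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer((h * 48271) %% 2147483647)
}

#' Write a tibble as TSV with a provenance comment header
#'
#' Output dialect used by the whole pipeline: UTF-8 TSV with a header line,
#' preceded by `# key=value` comment lines recording how the table was made.
#'
#' @param x A data frame.
#' @param path Output file path.
#' @param provenance Named character vector written as `# key=value` lines.
#' @return `path`, invisibly.
#' @export
write_tsv_prov <- function(x, path, provenance = character()) {
  header <- if (length(provenance) > 0) {
    sprintf("# %s=%s", names(provenance), as.character(provenance))
  } else {
    character()
  }
  body <- sub("\n$", "", readr::format_tsv(x))
  writeLines(c(header, body), path, useBytes = FALSE)
  invisible(path)
}

#' Read a pipeline TSV, skipping provenance comment lines
#'
#' @param path File path.
#' @param col_types Passed to [readr::read_tsv()].
#' @return A tibble.
#' @export
read_tsv_prov <- function(path, col_types = readr::cols()) {
  readr::read_tsv(path, comment = "#", col_types = col_types,
                  progress = FALSE)
}
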