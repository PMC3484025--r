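# internal helpers shared across modules

.valid_chroms <- c(as.character(1:22), "X", "Y", "XY", "MT", "M")

#' Normalize chromosome labels
#'
#' Strips a leading `"chr"` prefix (any case) and surrounding whitespace so
#' that `"chr1"`, `"Chr1"` and `"1"` all compare equal.
#'
#' @param x character vector of chromosome labels.
#' @return character vector of normalized labels.
#' @examples
#' normalize_chrom(c("chr1", "2", "chrX"))
#' @export
normalize_chrom <- function(x) {
  x <- sub("^chr", "", trimws(as.character(x)), ignore.case = TRUE)
  toupper(x)
}

# classed conditions so callers/tests can distinguish bad formats from
# invalid values
ee_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "eqtlenrich_error")))
}

validation_error <- function(msg) ee_stop(msg, "eqtlenrich_validation_error")
format_error <- function(msg) ee_stop(msg, "eqtlenrich_format_error")
config_error <- function(msg) ee_stop(msg, "eqtlenrich_config_error")

assert_chrom <- function(x, what = "chromosome") {
  bad <- setdiff(unique(normalize_chrom(x)), .valid_chroms)
  if (length(bad)) {
    validation_error(sprintf(
      "unknown %s label(s): %s", what, paste(bad, collapse = ", ")
    ))
  }
  invisible(TRUE)
}

# run expr under a temporary RNG seed, restoring caller state afterwards
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}
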