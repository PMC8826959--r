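# internal helpers shared across modules

# Evaluate `expr` under a locally seeded RNG, restoring (or removing) the
# caller's .Random.seed afterwards so no function mutates global RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# derive a stream of child seeds from one user-facing seed (kept < 2^31)
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pkg_version_string <- function() {
  as.character(utils::packageVersion("pardiv"))
}

# '#'-prefixed metadata lines atop every output TSV (version, seed, parameters);
# deliberately no timestamp so identical runs are byte-identical
tsv_header_lines <- function(params = list()) {
  params <- c(list(package = paste0("pardiv ", pkg_version_string())), params)
  vapply(names(params), function(k) {
    v <- params[[k]]
    sprintf("# %s: %s", k, paste(format(v, trim = TRUE), collapse = ","))
  }, character(1))
}

write_tsv_with_header <- function(df, path, params = list()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(tsv_header_lines(params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_plain <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "", ...)
}

stop_pardiv <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "pardiv_error", "error", "condition")))
}
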