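## Shared helpers.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded package internals do
#' not perturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## simple deterministic FASTA writer (70-column wrap, LF endings)
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con, sep = "\n")
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con, sep = "\n")
  }
  invisible(path)
}

stop_classed <- function(class, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
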