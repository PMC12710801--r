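# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mf <- function(..., class = "morphoflow_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_mf(..., class = "morphoflow_validation_error")
  invisible(TRUE)
}

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# md5 of an R object via its canonical JSON serialization
object_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"), f)
  unname(tools::md5sum(f))
}

is_count <- function(x) length(x) == 1 && is.finite(x) && x == round(x) && x >= 0
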