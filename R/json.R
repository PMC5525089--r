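# The JSON exchange format for algebras.  Scalars cross the boundary as
# exact strings (fractions), {a, b} pairs (quadratic field), or integer
# coefficient lists (finite fields); floats are never written, so a
# round-trip through JSON is lossless.
#
# Layout:
# {
#   "field": {"kind": "rational" | "quadratic" | "finite",
#             "discriminant": int?, "p": int?, "k": int?, "modulus": [int]?},
#   "basis": ["a1", ...],
#   "tensor": [[[scalar, ...], ...], ...],     # n x n x n, tensor[i][j][k]
#   "provenance": {...}
# }

.field_to_obj <- function(f) {
  switch(f$kind,
         rational  = list(kind = "rational"),
         quadratic = list(kind = "quadratic", discriminant = f$d),
         finite    = list(kind = "finite", p = f$p, k = f$k,
                          modulus = as.list(f$modulus)))
}

.field_from_obj <- function(obj, where = "/field") {
  kind <- obj$kind
  if (is.null(kind) || !kind %in% c("rational", "quadratic", "finite"))
    stop(where, "/kind: expected \"rational\", \"quadratic\" or \"finite\"",
         call. = FALSE)
  switch(kind,
         rational  = field_rational(),
         quadratic = {
           if (is.null(obj$discriminant))
             stop(where, "/discriminant: required for quadratic fields",
                  call. = FALSE)
           field_quadratic(obj$discriminant)
         },
         finite = {
           for (fld in c("p", "k", "modulus"))
             if (is.null(obj[[fld]]))
               stop(where, "/", fld, ": required for finite fields",
                    call. = FALSE)
           make_finite_field(obj$p, obj$k, unlist(obj$modulus))
         })
}

.sc_to_obj <- function(x) {
  f <- x$f
  switch(f$kind,
         rational  = .rat_format(x$num, x$den),
         quadratic = list(a = .rat_format(x$num[1], x$den[1]),
                          b = .rat_format(x$num[2], x$den[2])),
         finite    = as.list(x$num))
}

.sc_from_obj <- function(f, obj, where = "") {
  tryCatch({
    if (f$kind == "finite" && is.list(obj)) obj <- unlist(obj)
    scalar(f, obj)
  }, error = function(e)
    stop(where, ": ", conditionMessage(e), call. = FALSE))
}

#' Serialize an algebra to the JSON exchange format
#'
#' @param A A `laa_algebra`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
#' @examples
#' js <- algebra_to_json(mendelian_gametic(2))
#' B <- algebra_from_json(js)
algebra_to_json <- function(A, path = NULL) {
  n <- A$n
  tensor <- lapply(seq_len(n), function(i)
    lapply(seq_len(n), function(j)
      lapply(seq_len(n), function(k) .sc_to_obj(A$tensor$gamma[[i, j, k]]))))
  obj <- list(field = .field_to_obj(A$field),
              basis = as.list(A$basis),
              tensor = tensor,
              provenance = A$provenance)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(as.character(js))
}

#' Read an algebra from the JSON exchange format
#'
#' Performs structural validation; malformed documents are rejected with
#' the offending location given as a JSON pointer (e.g. `/tensor/2/1/3`).
#'
#' @param x A file path or a JSON string.
#' @return A `laa_algebra`.
#' @export
algebra_from_json <- function(x) {
  txt <- if (length(x) == 1 && !grepl("[{\n]", x) && file.exists(x))
    paste(readLines(x, warn = FALSE), collapse = "\n") else x
  obj <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed JSON: ", conditionMessage(e), call. = FALSE))
  for (fld in c("field", "basis", "tensor"))
    if (is.null(obj[[fld]]))
      stop("/", fld, ": required member missing", call. = FALSE)
  field <- .field_from_obj(obj$field)
  basis <- unlist(obj$basis)
  n <- length(basis)
  if (n < 1) stop("/basis: must list at least one label", call. = FALSE)
  if (length(obj$tensor) != n)
    stop("/tensor: expected ", n, " slices, found ", length(obj$tensor),
         call. = FALSE)
  gamma <- vector("list", n^3); dim(gamma) <- c(n, n, n)
  for (i in seq_len(n)) {
    si <- obj$tensor[[i]]
    if (length(si) != n)
      stop("/tensor/", i, ": expected ", n, " rows", call. = FALSE)
    for (j in seq_len(n)) {
      sij <- si[[j]]
      if (length(sij) != n)
        stop("/tensor/", i, "/", j, ": expected ", n, " entries", call. = FALSE)
      for (k in seq_len(n)) {
        gamma[[i, j, k]] <- .sc_from_obj(field, sij[[k]],
                                         paste0("/tensor/", i, "/", j, "/", k))
      }
    }
  }
  algebra(field, basis,
          structure(list(n = n, gamma = gamma), class = "laa_tensor"),
          provenance = if (is.null(obj$provenance)) list() else obj$provenance)
}

# identity report -> plain list for JSON output
.report_to_obj <- function(r) {
  obj <- list(identity = r$name, mode = r$mode, verdict = r$verdict)
  if (!is.null(r$sample_size)) {
    obj$sample_size <- r$sample_size
    obj$seed <- r$seed
  }
  if (!is.null(r$counterexample)) obj$counterexample <- r$counterexample
  obj
}
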