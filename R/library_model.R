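# Promoter-RBS components, their regulated production-rate functions, and
# library containers with JSON serialization.

#' Create a promoter-RBS component
#'
#' A promoter-RBS component is a paired promoter and ribosome binding site
#' treated as one transcription-translation unit, indexed by its identified
#' kinetic strength.  Three regulation classes are supported: constitutive
#' (a single strength `P_c`), repressor-regulated and activator-regulated
#' (maximal strength `P_M`, basal strength `P_m`, plus Hill parameters for
#' the transcription factor and its inducer).
#'
#' @param id Short component label (the field's naming style is `"J6"`,
#'   `"L3"`, `"T3"`, ...).
#' @param regulation_class One of `"constitutive"`, `"repressor_regulated"`,
#'   `"activator_regulated"`.
#' @param P_c Constitutive kinetic strength (a.u. min^-1); constitutive
#'   components only.
#' @param P_M,P_m Maximal and basal kinetic strengths (a.u. min^-1);
#'   regulated components only, with `P_M > P_m >= 0`.
#' @param K_tf Regulator concentration of half effect (a.u.).
#' @param n_tf Regulator Hill coefficient (>= 1).
#' @param K_I Inducer concentration of half effect, in the inducer's units
#'   (e.g. mM for IPTG, ng/ml for aTc).
#' @param n_I Inducer Hill coefficient (>= 1).
#' @param inducer_name Label of the inducer that relieves (repressor class)
#'   or enables (activator class) regulation.
#' @return An object of class `prbs_component`.
#' @examples
#' j6 <- prbs_component("J6", "constitutive", P_c = 8)
#' t3 <- prbs_component("T3", "repressor_regulated", P_M = 40, P_m = 0.5,
#'                      K_tf = 20, n_tf = 2, K_I = 5, n_I = 2,
#'                      inducer_name = "aTc")
#' repressor_rate(t3, x_rep = 20, I = 0)
#' @export
prbs_component <- function(id,
                           regulation_class = c("constitutive",
                                                "repressor_regulated",
                                                "activator_regulated"),
                           P_c = NULL, P_M = NULL, P_m = NULL,
                           K_tf = NULL, n_tf = NULL, K_I = NULL, n_I = NULL,
                           inducer_name = NULL) {
  regulation_class <- match.arg(regulation_class)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    gt_stop("`id` must be a non-empty string", "gt_argument_error")

  if (regulation_class == "constitutive") {
    check_scalar(P_c, "P_c", 0, strict = TRUE)
    if (!is.null(P_M) || !is.null(P_m) || !is.null(K_tf) || !is.null(n_tf) ||
        !is.null(K_I) || !is.null(n_I) || !is.null(inducer_name))
      gt_stop("constitutive components carry only `P_c`", "gt_argument_error")
    out <- list(id = id, regulation_class = regulation_class, P_c = P_c)
  } else {
    check_scalar(P_M, "P_M", 0, strict = TRUE)
    check_scalar(P_m, "P_m", 0)
    if (P_M <= P_m)
      gt_stop(sprintf("component '%s': P_M (%g) must exceed P_m (%g)",
                      id, P_M, P_m), "gt_argument_error")
    check_scalar(K_tf, "K_tf", 0, strict = TRUE)
    check_scalar(n_tf, "n_tf", 1)
    check_scalar(K_I, "K_I", 0, strict = TRUE)
    check_scalar(n_I, "n_I", 1)
    if (!is.character(inducer_name) || length(inducer_name) != 1L)
      gt_stop("regulated components need `inducer_name`", "gt_argument_error")
    if (!is.null(P_c))
      gt_stop("regulated components carry no `P_c`", "gt_argument_error")
    out <- list(id = id, regulation_class = regulation_class,
                P_M = P_M, P_m = P_m, K_tf = K_tf, n_tf = n_tf,
                K_I = K_I, n_I = n_I, inducer_name = inducer_name)
  }
  structure(out, class = "prbs_component")
}

#' @export
print.prbs_component <- function(x, ...) {
  if (x$regulation_class == "constitutive") {
    cat(sprintf("<prbs_component> %s [constitutive]  P_c = %g a.u./min\n",
                x$id, x$P_c))
  } else {
    cat(sprintf(
      "<prbs_component> %s [%s]  P_M = %g, P_m = %g a.u./min; K_tf = %g, n_tf = %g; %s: K_I = %g, n_I = %g\n",
      x$id, x$regulation_class, x$P_M, x$P_m, x$K_tf, x$n_tf,
      x$inducer_name, x$K_I, x$n_I))
  }
  invisible(x)
}

.check_class <- function(c, expected, fn) {
  if (!inherits(c, "prbs_component"))
    gt_stop(sprintf("%s() expects a prbs_component", fn), "gt_argument_error")
  if (c$regulation_class != expected)
    gt_stop(sprintf("%s() requires a %s component, got %s ('%s')",
                    fn, expected, c$regulation_class, c$id),
            "gt_class_mismatch")
}

# Hill repression with competitive inducer sequestration: the inducer binds
# the repressor, leaving x_free = x / (1 + (I/K_I)^n_I) to occupy the operator.
hill_repression <- function(P_M, P_m, x, I, K_tf, n_tf, K_I, n_I) {
  x_free <- x / (1 + (I / K_I)^n_I)
  P_m + (P_M - P_m) / (1 + (x_free / K_tf)^n_tf)
}

# Activator analogue: inducer converts the activator into its active form.
hill_activation <- function(P_M, P_m, x, I, K_tf, n_tf, K_I, n_I) {
  frac <- (I / K_I)^n_I
  x_act <- x * frac / (1 + frac)
  occ <- (x_act / K_tf)^n_tf
  P_m + (P_M - P_m) * occ / (1 + occ)
}

#' Production rate of a constitutive component
#'
#' @param c A constitutive [prbs_component()].
#' @return The production rate `P_c` (a.u. min^-1), independent of any
#'   regulator or inducer.
#' @export
constitutive_rate <- function(c) {
  .check_class(c, "constitutive", "constitutive_rate")
  c$P_c
}

#' Production rate of a repressor-regulated component
#'
#' Returns `P_m + (P_M - P_m) / (1 + (x_free/K_tf)^n_tf)` with the free
#' repressor `x_free = x_rep / (1 + (I/K_I)^n_I)`: the inducer sequesters
#' repressor and relieves repression.  The value always lies in
#' `[P_m, P_M]`, is non-increasing in `x_rep` and non-decreasing in `I`.
#'
#' @param c A repressor-regulated [prbs_component()].
#' @param x_rep Repressor concentration (a.u.), vectorised, `>= 0`.
#' @param I Inducer concentration (inducer units), vectorised, `>= 0`.
#' @return Production rate(s) in a.u. min^-1.
#' @export
repressor_rate <- function(c, x_rep, I = 0) {
  .check_class(c, "repressor_regulated", "repressor_rate")
  if (any(x_rep < 0) || any(I < 0))
    gt_stop("concentrations must be non-negative", "gt_domain_error")
  hill_repression(c$P_M, c$P_m, x_rep, I, c$K_tf, c$n_tf, c$K_I, c$n_I)
}

#' Production rate of an activator-regulated component
#'
#' Returns `P_m + (P_M - P_m) * h / (1 + h)` with
#' `h = (x_active/K_tf)^n_tf` and the inducer-activated fraction
#' `x_active = x_act * (I/K_I)^n_I / (1 + (I/K_I)^n_I)`.  Non-decreasing in
#' both arguments, bounded in `[P_m, P_M]`.
#'
#' @param c An activator-regulated [prbs_component()].
#' @param x_act Activator concentration (a.u.), `>= 0`.
#' @param I Inducer concentration, `>= 0`.
#' @return Production rate(s) in a.u. min^-1.
#' @export
activator_rate <- function(c, x_act, I = 0) {
  .check_class(c, "activator_regulated", "activator_rate")
  if (any(x_act < 0) || any(I < 0))
    gt_stop("concentrations must be non-negative", "gt_domain_error")
  hill_activation(c$P_M, c$P_m, x_act, I, c$K_tf, c$n_tf, c$K_I, c$n_I)
}

#' Production rate of any component
#'
#' Dispatches on the component's regulation class; `x_reg` and `I` are
#' ignored for constitutive components.
#'
#' @inheritParams repressor_rate
#' @param x_reg Regulator (repressor or activator) concentration (a.u.).
#' @return Production rate(s) in a.u. min^-1.
#' @export
production_rate <- function(c, x_reg = 0, I = 0) {
  switch(c$regulation_class,
         constitutive = rep_len(constitutive_rate(c),
                                max(length(x_reg), length(I))),
         repressor_regulated = repressor_rate(c, x_reg, I),
         activator_regulated = activator_rate(c, x_reg, I))
}

#' Create a promoter-RBS library
#'
#' A library is a named, ordered collection of components that share one
#' regulation class (and, for regulated classes, one inducer).
#'
#' @param name Library label, e.g. `"Lib_const"`, `"Lib_Tet"`.
#' @param components List of [prbs_component()] objects; non-empty, unique
#'   ids, all of the same regulation class.
#' @return An object of class `prbs_library`.
#' @export
prbs_library <- function(name, components) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    gt_stop("`name` must be a non-empty string", "gt_argument_error")
  if (!is.list(components) || length(components) == 0L)
    gt_stop("a library needs at least one component", "gt_parse_error")
  if (!all(vapply(components, inherits, logical(1), "prbs_component")))
    gt_stop("all library entries must be prbs_component objects",
            "gt_argument_error")
  ids <- vapply(components, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    gt_stop(sprintf("duplicate component ids: %s",
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")),
            "gt_parse_error")
  classes <- unique(vapply(components, `[[`, character(1), "regulation_class"))
  if (length(classes) != 1L)
    gt_stop("all components in a library must share one regulation class",
            "gt_parse_error")
  if (classes != "constitutive") {
    ind <- unique(vapply(components, `[[`, character(1), "inducer_name"))
    if (length(ind) != 1L)
      gt_stop("all regulated components in a library must share one inducer",
              "gt_parse_error")
  }
  names(components) <- ids
  structure(list(name = name, components = components),
            class = "prbs_library")
}

#' @export
print.prbs_library <- function(x, ...) {
  cls <- x$components[[1]]$regulation_class
  cat(sprintf("<prbs_library> %s: %d %s component(s): %s\n",
              x$name, length(x$components), cls,
              paste(names(x$components), collapse = ", ")))
  invisible(x)
}

#' @export
length.prbs_library <- function(x) length(x$components)

#' Read / write a promoter-RBS library as JSON
#'
#' The on-disk dialect is a JSON object with fields `name` and `components`
#' (an array of objects carrying an explicit `regulation_class`
#' discriminator); numbers are stored at full double precision, so a
#' save/load round trip is lossless.  All component and library invariants
#' are re-validated on load.
#'
#' @param path File path.
#' @return `read_library()` returns a [prbs_library()];
#'   `write_library()` returns `path` invisibly.
#' @export
read_library <- function(path) {
  if (!file.exists(path))
    gt_stop(sprintf("library file not found: %s", path), "gt_parse_error")
  raw <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) gt_stop(sprintf("malformed library JSON (%s): %s",
                                        path, conditionMessage(e)),
                                "gt_parse_error"))
  if (is.null(raw$name) || is.null(raw$components))
    gt_stop("library JSON needs `name` and `components`", "gt_parse_error")
  comps <- lapply(raw$components, function(cc) {
    do.call(prbs_component, cc)
  })
  prbs_library(raw$name, comps)
}

#' @rdname read_library
#' @param lib A [prbs_library()].
#' @export
write_library <- function(lib, path) {
  if (!inherits(lib, "prbs_library"))
    gt_stop("`lib` must be a prbs_library", "gt_argument_error")
  payload <- list(
    name = lib$name,
    components = lapply(unname(lib$components), function(cc) {
      unclass(cc)
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}
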