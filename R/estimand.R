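#' Do-free estimand expression trees
#'
#' An `estimand` is a finite expression tree over observed variables with
#' four node kinds: `conditional(vars, given)` — a conditional (or marginal)
#' of the observational joint; `marginalize(vars, child)` — sum/integral
#' over `vars`; `product(children)`; and `fraction(num, den)`.  It contains
#' no do-operator: it is what identification returns and what
#' [evaluate_estimand()] computes numerically.
#'
#' @param vars,given character vectors of variable names.
#' @param child,num,den estimand nodes.
#' @param children list of estimand nodes.
#' @return An object of class `estimand`.
#' @name estimand
NULL

#' @rdname estimand
#' @export
est_conditional <- function(vars, given = character()) {
  stopifnot(length(vars) >= 1)
  structure(list(kind = "conditional", vars = sort(unique(vars)),
                 given = sort(unique(given))), class = "estimand")
}

#' @rdname estimand
#' @export
est_marginalize <- function(vars, child) {
  vars <- sort(unique(vars))
  if (!length(vars)) return(child)
  if (child$kind == "marginalize") {
    return(est_marginalize(union(vars, child$vars), child$child))
  }
  # marginal of a raw (unconditional) leaf is itself a leaf
  if (child$kind == "conditional" && !length(child$given) &&
      length(setdiff(child$vars, vars))) {
    return(est_conditional(setdiff(child$vars, vars)))
  }
  structure(list(kind = "marginalize", vars = vars, child = child),
            class = "estimand")
}

#' @rdname estimand
#' @export
est_product <- function(children) {
  flat <- list()
  for (ch in children) {
    if (ch$kind == "product") flat <- c(flat, ch$children)
    else flat <- c(flat, list(ch))
  }
  if (length(flat) == 1) return(flat[[1]])
  structure(list(kind = "product", children = flat), class = "estimand")
}

#' @rdname estimand
#' @export
est_fraction <- function(num, den) {
  structure(list(kind = "fraction", num = num, den = den),
            class = "estimand")
}

#' Free variables of an estimand
#'
#' @param estimand an `estimand`.
#' @return Character vector of variable names the expression depends on.
#' @export
est_vars <- function(estimand) {
  switch(estimand$kind,
    conditional = union(estimand$vars, estimand$given),
    marginalize = setdiff(est_vars(estimand$child), estimand$vars),
    product = sort(unique(unlist(lapply(estimand$children, est_vars)))),
    fraction = sort(union(est_vars(estimand$num), est_vars(estimand$den))))
}

#' Render an estimand as plain-text math
#'
#' @param estimand an `estimand`.
#' @return A character scalar such as
#'   `"sum_{z} P(z|x) sum_{x} P(y|x,z) P(x)"`.
#' @export
render_estimand <- function(estimand) {
  switch(estimand$kind,
    conditional = {
      g <- if (length(estimand$given))
        paste0("|", paste(estimand$given, collapse = ",")) else ""
      paste0("P(", paste(estimand$vars, collapse = ","), g, ")")
    },
    marginalize = paste0("sum_{", paste(estimand$vars, collapse = ","),
                         "} [ ", render_estimand(estimand$child), " ]"),
    product = paste(vapply(estimand$children, render_estimand, ""),
                    collapse = " * "),
    fraction = paste0("[ ", render_estimand(estimand$num), " ] / [ ",
                      render_estimand(estimand$den), " ]"))
}

#' @export
print.estimand <- function(x, ...) {
  cat(render_estimand(x), "\n")
  invisible(x)
}

#' Serialize an estimand to JSON
#'
#' @param estimand an `estimand`.
#' @param path optional file to write to.
#' @return JSON string (invisibly when written to `path`).
#' @export
estimand_to_json <- function(estimand, path = NULL) {
  to_list <- function(e) {
    switch(e$kind,
      conditional = list(kind = "conditional", vars = as.list(e$vars),
                         given = as.list(e$given)),
      marginalize = list(kind = "marginalize", vars = as.list(e$vars),
                         child = to_list(e$child)),
      product = list(kind = "product",
                     children = lapply(e$children, to_list)),
      fraction = list(kind = "fraction", num = to_list(e$num),
                      den = to_list(e$den)))
  }
  js <- jsonlite::toJSON(to_list(estimand), auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

# ---------------------------------------------------------------------------
# numeric evaluation against a discrete joint probability table

eval_node <- function(e, joint) {
  vars_in_joint <- setdiff(names(joint), "p")
  switch(e$kind,
    conditional = {
      missing <- setdiff(c(e$vars, e$given), vars_in_joint)
      if (length(missing)) {
        stop("estimand variable(s) absent from table: ",
             paste(missing, collapse = ", "))
      }
      num <- joint |>
        dplyr::group_by(dplyr::across(dplyr::all_of(c(e$vars, e$given)))) |>
        dplyr::summarise(val = sum(.data$p), .groups = "drop")
      if (!length(e$given)) return(num)
      den <- joint |>
        dplyr::group_by(dplyr::across(dplyr::all_of(e$given))) |>
        dplyr::summarise(.den = sum(.data$p), .groups = "drop")
      num |>
        dplyr::left_join(den, by = e$given) |>
        dplyr::mutate(val = safe_div(.data$val, .data$.den)) |>
        dplyr::select(-".den")
    },
    marginalize = {
      tab <- eval_node(e$child, joint)
      keep <- setdiff(names(tab), c("val", e$vars))
      if (!length(keep)) {
        return(tibble::tibble(val = sum(tab$val)))
      }
      tab |>
        dplyr::group_by(dplyr::across(dplyr::all_of(keep))) |>
        dplyr::summarise(val = sum(.data$val), .groups = "drop")
    },
    product = {
      tabs <- lapply(e$children, eval_node, joint = joint)
      out <- tabs[[1]]
      for (tab in tabs[-1]) {
        by <- intersect(setdiff(names(out), "val"),
                        setdiff(names(tab), "val"))
        if (length(by)) {
          out <- dplyr::inner_join(out, tab, by = by,
                                   suffix = c("", ".y"),
                                   relationship = "many-to-many")
        } else {
          out <- dplyr::cross_join(out, tab, suffix = c("", ".y"))
        }
        out <- out |>
          dplyr::mutate(val = .data$val * .data$val.y) |>
          dplyr::select(-"val.y")
      }
      out
    },
    fraction = {
      num <- eval_node(e$num, joint)
      den <- eval_node(e$den, joint)
      by <- intersect(setdiff(names(num), "val"),
                      setdiff(names(den), "val"))
      if (length(by)) {
        out <- dplyr::inner_join(num, den, by = by, suffix = c("", ".y"),
                                 relationship = "many-to-many")
      } else {
        out <- dplyr::cross_join(num, den, suffix = c("", ".y"))
      }
      out |>
        dplyr::mutate(val = safe_div(.data$val, .data$val.y)) |>
        dplyr::select(-"val.y")
    })
}

# positivity convention: a conditional with a zero-mass conditioning event
# contributes zero (the front-door precondition P(x, z) > 0 rules the case
# out for well-posed problems; 0/0 -> 0 keeps evaluation total)
safe_div <- function(a, b) ifelse(b == 0, 0, a / b)

#' Evaluate an estimand on a discrete joint probability table
#'
#' Evaluates the expression tree by summation against a full table over the
#' observed variables, substitutes the intervention values, and returns the
#' interventional distribution over the outcome variables.  If the
#' expression carries free context variables beyond targets and outcomes
#' (ratio-form estimands such as the napkin's are constant in such
#' variables for any joint that is Markov to the graph), the value is
#' averaged over their observational marginal.
#'
#' @param estimand an `estimand`.
#' @param joint a data frame with one column per observed variable plus a
#'   `p` column of non-negative probabilities summing to 1.
#' @param targets named vector of intervention values (values must occur in
#'   the table's support); may be `NULL` for a purely observational
#'   expression.
#' @param outcomes character vector of outcome variables; defaults to all
#'   free variables that are not targets.
#' @return A tibble with the outcome columns and a `prob` column summing
#'   to 1.
#' @export
evaluate_estimand <- function(estimand, joint, targets = NULL,
                              outcomes = NULL) {
  joint <- tibble::as_tibble(joint)
  stopifnot("p" %in% names(joint))
  tab <- eval_node(estimand, joint)
  fv <- setdiff(names(tab), "val")
  if (is.null(outcomes)) outcomes <- setdiff(fv, names(targets))
  if (length(targets)) {
    for (v in intersect(names(targets), fv)) {
      if (!any(tab[[v]] == targets[[v]])) {
        stop("target value ", targets[[v]], " for ", v,
             " is outside the table's support")
      }
      tab <- tab[tab[[v]] == targets[[v]], , drop = FALSE]
      tab[[v]] <- NULL
    }
  }
  ctx <- setdiff(setdiff(names(tab), "val"), outcomes)
  if (length(ctx)) {
    w <- joint |>
      dplyr::group_by(dplyr::across(dplyr::all_of(ctx))) |>
      dplyr::summarise(.w = sum(.data$p), .groups = "drop")
    w$.w <- w$.w / sum(w$.w)
    tab <- tab |>
      dplyr::inner_join(w, by = ctx) |>
      dplyr::mutate(val = .data$val * .data$.w) |>
      dplyr::select(-".w")
  }
  tab |>
    dplyr::group_by(dplyr::across(dplyr::all_of(outcomes))) |>
    dplyr::summarise(prob = sum(.data$val), .groups = "drop")
}
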