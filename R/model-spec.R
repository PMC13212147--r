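# sem_fiml: recursive linear path model specification.

#' Build a recursive path-model specification
#'
#' Default structure for the mediation analysis: treatment -> each mediator
#' (`a` paths), treatment -> outcome (direct effect), mediators -> outcome
#' (`b` paths), non-market mediators -> market activity (`d` paths), and
#' every baseline covariate -> every endogenous variable. Residual
#' covariances are freed within the declared blocks (by default all garden
#' and poultry mediators, and the two knowledge mediators).
#'
#' @param mediators character vector of mediator variable names (model
#'   names, e.g. `c("crop","prac","pltry","egg","fgknow","ddknow")`).
#' @param outcome outcome variable name.
#' @param treatment treatment indicator name.
#' @param covariates character vector of exogenous covariate names.
#' @param market name of the market-activity mediator that is itself
#'   regressed on `via_market`; `NULL` for no such sequential mediator.
#' @param via_market mediators with a path into `market` (default: all
#'   non-market mediators).
#' @param residual_blocks list of character vectors of endogenous variables
#'   whose residuals covary freely.
#' @return a `path_model_spec` object.
#' @export
build_model_spec <- function(mediators,
                             outcome = "dds",
                             treatment = "trt",
                             covariates = character(),
                             market = if ("market" %in% mediators) "market" else NULL,
                             via_market = setdiff(mediators, market),
                             residual_blocks = list(c("crop", "prac", "pltry", "egg"),
                                                    c("fgknow", "ddknow"))) {
  mediators <- unique(mediators)
  nonmkt <- setdiff(mediators, market)
  eqs <- list()
  for (m in nonmkt) eqs[[m]] <- c(treatment, covariates)
  if (!is.null(market)) {
    eqs[[market]] <- c(treatment, via_market, covariates)
  }
  eqs[[outcome]] <- c(treatment, mediators, covariates)
  residual_blocks <- Filter(function(b) length(b) >= 2,
                            lapply(residual_blocks, function(b) intersect(b, names(eqs))))
  new_path_model_spec(eqs, residual_blocks)
}

new_path_model_spec <- function(eqs, residual_blocks) {
  endo <- names(eqs)
  if (anyDuplicated(endo)) abort("duplicate endogenous variable names.")
  all_regs <- unique(unlist(eqs))
  exo <- setdiff(all_regs, endo)
  ord <- topo_sort(eqs, endo)            # errors on cycles
  endo <- ord
  eqs <- eqs[endo]
  for (b in residual_blocks) {
    bad <- setdiff(b, endo)
    if (length(bad)) abort(paste("residual block references unknown variable:",
                                 paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(unlist(residual_blocks))) {
    abort("a variable appears in more than one residual block.")
  }
  structure(list(endo = endo, exo = exo, eqs = eqs,
                 residual_blocks = residual_blocks),
            class = c("path_model_spec", "list"))
}

topo_sort <- function(eqs, endo) {
  deps <- lapply(eqs, intersect, y = endo)
  ordered <- character()
  left <- endo
  while (length(left)) {
    ready <- left[vapply(left, function(v) all(deps[[v]] %in% ordered), logical(1))]
    if (!length(ready)) {
      abort("cyclic path specification: the directed system must be recursive.")
    }
    ordered <- c(ordered, ready)
    left <- setdiff(left, ready)
  }
  ordered
}

#' @export
print.path_model_spec <- function(x, ...) {
  cat("Recursive path model:", length(x$endo), "endogenous,",
      length(x$exo), "exogenous variables\n")
  cat(model_syntax(x), sep = "\n")
  invisible(x)
}

#' Render a specification in model-syntax form
#' @param spec a `path_model_spec`.
#' @return character vector of syntax lines.
#' @export
model_syntax <- function(spec) {
  lines <- vapply(spec$endo, function(v)
    paste0(v, " ~ ", paste(spec$eqs[[v]], collapse = " + ")), character(1))
  for (b in spec$residual_blocks) {
    prs <- utils::combn(b, 2)
    lines <- c(lines, apply(prs, 2, function(p) paste0(p[1], " ~~ ", p[2])))
  }
  unname(lines)
}

#' Parse model syntax into a specification
#'
#' Accepts the usual SEM mini-language: one regression per line
#' (`y ~ t + m1 + m2`) and residual covariances as `m1 ~~ m2`. Covariance
#' pairs are merged into maximal residual blocks.
#'
#' @param text character scalar or vector of syntax lines.
#' @return a `path_model_spec`.
#' @export
parse_model_syntax <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "[\n;]"))
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  eqs <- list()
  pairs <- list()
  for (ln in lines) {
    if (grepl("~~", ln, fixed = TRUE)) {
      pr <- trimws(strsplit(ln, "~~", fixed = TRUE)[[1]])
      if (length(pr) != 2) abort(paste("cannot parse covariance line:", ln))
      pairs[[length(pairs) + 1L]] <- pr
    } else if (grepl("~", ln, fixed = TRUE)) {
      sides <- trimws(strsplit(ln, "~", fixed = TRUE)[[1]])
      if (length(sides) != 2) abort(paste("cannot parse regression line:", ln))
      regs <- trimws(strsplit(sides[2], "+", fixed = TRUE)[[1]])
      regs <- setdiff(regs, "1")
      if (!is.null(eqs[[sides[1]]])) abort(paste("duplicate equation for", sides[1]))
      eqs[[sides[1]]] <- regs
    } else {
      abort(paste("cannot parse line:", ln))
    }
  }
  # merge covariance pairs into blocks (connected components)
  blocks <- list()
  for (pr in pairs) {
    hit <- which(vapply(blocks, function(b) any(pr %in% b), logical(1)))
    if (length(hit) == 0) {
      blocks[[length(blocks) + 1L]] <- pr
    } else {
      merged <- unique(c(unlist(blocks[hit]), pr))
      blocks <- blocks[-hit]
      blocks[[length(blocks) + 1L]] <- merged
    }
  }
  new_path_model_spec(eqs, blocks)
}
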