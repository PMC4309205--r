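#' Read and write models in SBML-qual
#'
#' SBML Level 3 with the Qualitative Models (`qual`) package is the
#' community interchange format for logical models; GINsim, for instance,
#' exports its models to it.  The writer emits one transition per non-input
#' component with a `defaultTerm` and one `functionTerm` per non-default
#' output level (MathML over `and`/`or`/`not`/`eq`/`geq`/`leq`).  The
#' reader supports that subset and interprets multiple function terms
#' deterministically: the first term (in document order) whose condition
#' matches wins, mirroring the first-match clause semantics of the mnet
#' format.  Qualitative species marked `constant="true"` (or lacking both a
#' transition and regulators) are treated as input components.  Declared
#' interaction signs are taken from `qual:sign` attributes when present.
#'
#' @param path file path.
#' @return `read_sbml_qual()` returns a validated [logical_model()].
#' @export
read_sbml_qual <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(sbml = "http://www.sbml.org/sbml/level3/version1/core",
          qual = "http://www.sbml.org/sbml/level3/version1/qual/version1",
          mml = "http://www.w3.org/1998/Math/MathML")
  sp <- xml2::xml_find_all(doc, ".//qual:qualitativeSpecies", ns)
  if (length(sp) == 0L)
    stop_parse(paste0(path, ": no qual:qualitativeSpecies elements found"))
  comps <- data.frame(
    name = xml2::xml_attr(sp, "qual:id", ns = ns),
    max_level = as.integer(xml2::xml_attr(sp, "qual:maxLevel", ns = ns)),
    is_input = xml2::xml_attr(sp, "qual:constant", ns = ns) %in% "true",
    stringsAsFactors = FALSE)
  if (anyNA(comps$max_level))
    stop_parse(paste0(path, ": qualitativeSpecies without maxLevel"))
  card <- stats::setNames(comps$max_level + 1L, comps$name)

  trs <- xml2::xml_find_all(doc, ".//qual:transition", ns)
  rule_specs <- list()
  declared <- list()
  for (tr in trs) {
    out <- xml2::xml_find_first(tr, ".//qual:output", ns)
    target <- xml2::xml_attr(out, "qual:qualitativeSpecies", ns = ns)
    if (is.na(target))
      stop_parse(paste0(path, ": transition without an output species"))
    ins <- xml2::xml_find_all(tr, ".//qual:input", ns)
    for (i in seq_along(ins)) {
      src <- xml2::xml_attr(ins[[i]], "qual:qualitativeSpecies", ns = ns)
      thr <- xml2::xml_attr(ins[[i]], "qual:thresholdLevel", ns = ns)
      sgn <- xml2::xml_attr(ins[[i]], "qual:sign", ns = ns)
      declared[[length(declared) + 1L]] <- data.frame(
        source = src, target = target,
        threshold = if (is.na(thr)) 1L else as.integer(thr),
        sign = switch(if (is.na(sgn)) "unknown" else sgn,
                      positive = "activation", negative = "inhibition",
                      dual = "dual", "unknown"),
        stringsAsFactors = FALSE)
    }
    dflt <- xml2::xml_find_first(tr, ".//qual:defaultTerm", ns)
    clauses <- list()
    fts <- xml2::xml_find_all(tr, ".//qual:functionTerm", ns)
    for (ft in fts) {
      lvl <- as.integer(xml2::xml_attr(ft, "qual:resultLevel", ns = ns))
      math <- xml2::xml_find_first(ft, "./mml:math/*", ns)
      if (inherits(math, "xml_missing"))
        stop_parse(paste0(path, ": functionTerm without MathML for ",
                          target))
      clauses[[length(clauses) + 1L]] <-
        list(cond = mathml_to_cond(math, ns, path), level = lvl)
    }
    if (!inherits(dflt, "xml_missing")) {
      clauses[[length(clauses) + 1L]] <-
        list(cond = list(type = "const", value = TRUE),
             level = as.integer(xml2::xml_attr(dflt, "qual:resultLevel",
                                               ns = ns)))
    }
    rule_specs[[target]] <- clauses
  }
  # Species without transitions and without regulators are inputs.
  no_rule <- setdiff(comps$name, names(rule_specs))
  comps$is_input <- comps$is_input | comps$name %in% no_rule
  m <- model_from_clauses(comps, rule_specs, context = path)
  # keep declared signs where the derived interaction exists
  if (length(declared)) {
    dd <- do.call(rbind, declared)
    for (k in seq_len(nrow(m$interactions))) {
      hit <- dd$source == m$interactions$source[k] &
        dd$target == m$interactions$target[k] & dd$sign != "unknown"
      if (any(hit)) m$interactions$sign[k] <- dd$sign[hit][1]
    }
  }
  m
}

# MathML <apply> subset -> condition AST.
mathml_to_cond <- function(node, ns, path) {
  name <- xml2::xml_name(node)
  if (name != "apply")
    stop_parse(paste0(path, ": unsupported MathML node <", name,
                      "> (only apply/and/or/not/eq/geq/leq are supported)"))
  kids <- xml2::xml_find_all(node, "./*")
  op <- xml2::xml_name(kids[[1]])
  args <- kids[-1]
  if (op %in% c("and", "or")) {
    conds <- lapply(args, mathml_to_cond, ns = ns, path = path)
    out <- conds[[1]]
    for (k in seq_along(conds)[-1])
      out <- list(type = if (op == "and") "and" else "or",
                  a = out, b = conds[[k]])
    return(out)
  }
  if (op == "not")
    return(list(type = "not", a = mathml_to_cond(args[[1]], ns, path)))
  if (op %in% c("eq", "geq", "leq")) {
    ci <- xml2::xml_text(args[[1]])
    cn <- suppressWarnings(as.integer(xml2::xml_text(args[[2]])))
    if (is.na(cn))
      stop_parse(paste0(path, ": non-integer constant in MathML comparison"))
    return(list(type = "cmp", name = trimws(ci),
                op = switch(op, eq = "=", geq = ">=", leq = "<="),
                level = cn))
  }
  stop_parse(paste0(path, ": unsupported MathML operator <", op, ">"))
}

#' @rdname read_sbml_qual
#' @param model a [logical_model()].
#' @export
write_sbml_qual <- function(model, path) {
  esc <- function(x) gsub("&", "&amp;", x)
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\"",
           " level=\"3\" version=\"1\"",
           " xmlns:qual=\"http://www.sbml.org/sbml/level3/version1/qual/version1\"",
           " qual:required=\"true\">"),
    "  <model id=\"logimc_model\">")
  red <- attr(model, "reduced_from")
  if (!is.null(red))
    lines <- c(lines,
               sprintf("    <!-- reduced: removed=%s source_fnv=%s -->",
                       paste(red$removed, collapse = ","), red$source_hash))
  lines <- c(lines, "    <qual:listOfQualitativeSpecies>")
  for (i in seq_len(nrow(model$components)))
    lines <- c(lines, sprintf(
      "      <qual:qualitativeSpecies qual:id=\"%s\" qual:maxLevel=\"%d\" qual:constant=\"%s\"/>",
      model$components$name[i], model$components$max_level[i],
      if (model$components$is_input[i]) "true" else "false"))
  lines <- c(lines, "    </qual:listOfQualitativeSpecies>",
             "    <qual:listOfTransitions>")
  sign_attr <- c(activation = "positive", inhibition = "negative",
                 dual = "dual")
  for (nm in intersect(model$components$name, names(model$rules))) {
    r <- model$rules[[nm]]
    lines <- c(lines, sprintf("      <qual:transition qual:id=\"tr_%s\">", nm))
    if (length(r$regulators)) {
      lines <- c(lines, "        <qual:listOfInputs>")
      for (g in r$regulators) {
        ia <- model$interactions
        hit <- ia$source == g & ia$target == nm
        thr <- if (any(hit)) ia$threshold[hit][1] else 1L
        sgn <- if (any(hit) && ia$sign[hit][1] %in% names(sign_attr))
          sprintf(" qual:sign=\"%s\"", sign_attr[[ia$sign[hit][1]]]) else ""
        lines <- c(lines, sprintf(
          "          <qual:input qual:id=\"in_%s_%s\" qual:qualitativeSpecies=\"%s\" qual:transitionEffect=\"none\" qual:thresholdLevel=\"%d\"%s/>",
          nm, g, g, thr, sgn))
      }
      lines <- c(lines, "        </qual:listOfInputs>")
    }
    lines <- c(lines,
               "        <qual:listOfOutputs>",
               sprintf("          <qual:output qual:id=\"out_%s\" qual:qualitativeSpecies=\"%s\" qual:transitionEffect=\"assignmentLevel\"/>",
                       nm, nm),
               "        </qual:listOfOutputs>",
               "        <qual:listOfFunctionTerms>")
    # default = most frequent output level; one functionTerm per other level
    tab <- tabulate(r$outputs + 1L, nbins = max(r$outputs) + 1L)
    default <- which.max(tab) - 1L
    lines <- c(lines, sprintf("          <qual:defaultTerm qual:resultLevel=\"%d\"/>",
                              default))
    if (length(r$regulators)) {
      g <- level_grid(r$card, r$regulators)
      for (lev in sort(unique(r$outputs))) {
        if (lev == default) next
        rows <- which(r$outputs == lev)
        row_math <- vapply(rows, function(i) {
          atoms <- sprintf("<apply><eq/><ci>%s</ci><cn type=\"integer\">%d</cn></apply>",
                           esc(r$regulators), g[i, ])
          if (length(atoms) > 1L)
            paste0("<apply><and/>", paste(atoms, collapse = ""), "</apply>")
          else atoms
        }, character(1))
        math <- if (length(row_math) > 1L)
          paste0("<apply><or/>", paste(row_math, collapse = ""), "</apply>")
        else row_math
        lines <- c(lines,
                   sprintf("          <qual:functionTerm qual:resultLevel=\"%d\">", lev),
                   "            <math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
                   paste0("              ", math),
                   "            </math>",
                   "          </qual:functionTerm>")
      }
    }
    lines <- c(lines, "        </qual:listOfFunctionTerms>",
               "      </qual:transition>")
  }
  lines <- c(lines, "    </qual:listOfTransitions>", "  </model>", "</sbml>")
  writeLines(lines, path)
  invisible(lines)
}
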