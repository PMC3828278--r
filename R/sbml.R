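# --- MathML -> R expression translation -------------------------------
#
# Covers the MathML subset used by SBML kinetic laws: n-ary arithmetic,
# power/root, exp/ln/log, trigonometry, piecewise, relational and logical
# operators, numeric constants (integer, real, e-notation, rational), the
# time csymbol, and calls to SBML function definitions (inlined). The
# delay csymbol is unsupported and raises an error naming the construct.

mathml_to_r <- function(node, fundefs = list()) {
  name <- xml2::xml_name(node)
  switch(name,
    cn = mathml_cn(node),
    ci = trimws(xml2::xml_text(node)),
    csymbol = {
      url <- xml2::xml_attr(node, "definitionURL") %||% ""
      if (grepl("time", url)) "time"
      else if (grepl("delay", url))
        stop("unsupported SBML construct: delay")
      else if (grepl("avogadro", url)) "6.02214179e23"
      else stop("unsupported csymbol: ", url)
    },
    apply = mathml_apply(node, fundefs),
    piecewise = mathml_piecewise(node, fundefs),
    pi = "pi",
    exponentiale = "exp(1)",
    true = "TRUE",
    false = "FALSE",
    notanumber = "NaN",
    infinity = "Inf",
    math = mathml_to_r(xml2::xml_child(node), fundefs),
    stop("unsupported MathML element: ", name)
  )
}

mathml_cn <- function(node) {
  type <- xml2::xml_attr(node, "type") %||% "real"
  if (type %in% c("e-notation", "rational")) {
    # the two operands are text nodes separated by <sep/>
    parts <- trimws(vapply(xml2::xml_find_all(node, "./text()"),
                           xml2::xml_text, ""))
    parts <- parts[nzchar(parts)]
    if (type == "e-notation")
      return(paste0("(", parts[1], "e", parts[2], ")"))
    return(paste0("(", parts[1], "/", parts[2], ")"))
  }
  paste0("(", trimws(xml2::xml_text(node)), ")")
}

mathml_children <- function(node) {
  kids <- xml2::xml_children(node)
  kids[xml2::xml_name(kids) != "annotation"]
}

mathml_apply <- function(node, fundefs) {
  kids <- mathml_children(node)
  op <- xml2::xml_name(kids[[1]])
  operands <- kids[-1]
  # qualifier elements (logbase, degree) are consumed by their operators
  operands <- operands[!xml2::xml_name(operands) %in% c("logbase", "degree")]
  args <- lapply(operands, mathml_to_r, fundefs = fundefs)
  par1 <- function(x) paste0("(", x, ")")
  nary <- function(sym) paste0("(", paste(unlist(args), collapse = sym), ")")
  binfun <- function(f) paste0(f, "(", paste(unlist(args), collapse = ", "), ")")
  switch(op,
    plus = if (length(args) == 0) "(0)" else nary(" + "),
    times = if (length(args) == 0) "(1)" else nary(" * "),
    minus = if (length(args) == 1) par1(paste0("-", args[[1]]))
            else nary(" - "),
    divide = nary(" / "),
    power = paste0("(", args[[1]], "^", args[[2]], ")"),
    root = {
      deg <- xml2::xml_find_first(node, "./*[local-name()='degree']")
      if (inherits(deg, "xml_missing"))
        paste0("sqrt(", args[[length(args)]], ")")
      else {
        d <- mathml_to_r(xml2::xml_child(deg), fundefs)
        paste0("(", args[[length(args)]], "^(1/", d, "))")
      }
    },
    exp = binfun("exp"),
    ln = paste0("log(", args[[1]], ")"),
    log = {
      lb <- xml2::xml_find_first(node, "./*[local-name()='logbase']")
      base <- if (inherits(lb, "xml_missing")) "10"
              else mathml_to_r(xml2::xml_child(lb), fundefs)
      paste0("(log(", args[[length(args)]], ") / log(", base, "))")
    },
    abs = binfun("abs"),
    floor = binfun("floor"),
    ceiling = binfun("ceiling"),
    sin = binfun("sin"), cos = binfun("cos"), tan = binfun("tan"),
    arcsin = paste0("asin(", args[[1]], ")"),
    arccos = paste0("acos(", args[[1]], ")"),
    arctan = paste0("atan(", args[[1]], ")"),
    sinh = binfun("sinh"), cosh = binfun("cosh"), tanh = binfun("tanh"),
    lt = nary(" < "), leq = nary(" <= "),
    gt = nary(" > "), geq = nary(" >= "),
    eq = nary(" == "), neq = nary(" != "),
    and = nary(" & "), or = nary(" | "),
    not = paste0("(!", args[[1]], ")"),
    ci = {
      # call to an SBML function definition: inline the lambda body
      fname <- trimws(xml2::xml_text(kids[[1]]))
      fd <- fundefs[[fname]]
      if (is.null(fd))
        stop("call to unknown function definition '", fname, "'")
      if (length(fd$args) != length(args))
        stop("function '", fname, "' called with ", length(args),
             " arguments, expects ", length(fd$args))
      subst_symbols(fd$body,
                    setNames(vapply(args, identity, ""), fd$args))
    },
    stop("unsupported MathML operator: ", op)
  )
}

mathml_piecewise <- function(node, fundefs) {
  kids <- mathml_children(node)
  expr <- "(NaN)"
  other <- kids[xml2::xml_name(kids) == "otherwise"]
  if (length(other))
    expr <- mathml_to_r(xml2::xml_child(other[[1]]), fundefs)
  pieces <- kids[xml2::xml_name(kids) == "piece"]
  for (p in rev(pieces)) {
    pk <- mathml_children(p)
    val <- mathml_to_r(pk[[1]], fundefs)
    cond <- mathml_to_r(pk[[2]], fundefs)
    expr <- paste0("ifelse(", cond, ", ", val, ", ", expr, ")")
  }
  expr
}

# textual symbol substitution done on the parse tree, so that renaming a
# local parameter "k1" never touches e.g. "k10"
subst_symbols <- function(expr_str, mapping) {
  sub_lang <- function(e) {
    if (is.name(e)) {
      nm <- as.character(e)
      if (nm %in% names(mapping)) return(str2lang(mapping[[nm]]))
      return(e)
    }
    if (is.call(e)) {
      for (i in seq_along(e)[-1]) {
        if (!is.null(e[[i]])) e[[i]] <- sub_lang(e[[i]])
      }
      return(e)
    }
    e
  }
  deparse1(sub_lang(str2lang(expr_str)))
}

sbml_find <- function(node, what) {
  xml2::xml_find_all(node, paste0(".//*[local-name()='", what, "']"))
}

sbml_attr <- function(node, attr, default = NA) {
  v <- xml2::xml_attr(node, attr)
  if (is.na(v)) default else v
}

#' Load a kinetic model from an SBML file
#'
#' Reads SBML Level 2 or 3: species (initial concentrations; amounts are
#' converted using compartment volumes), compartments, global and
#' reaction-local parameters, reactions with MathML kinetic laws, and
#' rate rules. Function definitions and assignment rules are inlined at
#' load time. Reaction-local parameters are lifted into the flat
#' parameter list under the id `"<reaction>.<name>"` (a collision with an
#' existing id gains a numeric suffix, with a warning). Events in the
#' file are ignored with a warning -- oscillation periods are measured by
#' this package's own detector, not by events read from files. Algebraic
#' rules and delays are unsupported and raise an error naming the
#' construct.
#'
#' @param path path to an SBML file.
#' @return a [kinetic_model()]. Parameters whose rate law scales linearly
#'   in them are tagged with role `"limiting-rate"`.
#' @export
load_sbml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("SBML format error in '", path, "': ", conditionMessage(e)))
  if (!xml2::xml_name(doc) %in% "sbml")
    stop("SBML format error: root element is <", xml2::xml_name(doc),
         ">, not <sbml>")
  mnode <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  if (inherits(mnode, "xml_missing"))
    stop("SBML format error: no <model> element")

  if (length(sbml_find(mnode, "algebraicRule")))
    stop("unsupported SBML construct: algebraicRule")
  if (length(sbml_find(mnode, "delay")))
    stop("unsupported SBML construct: delay")
  if (length(sbml_find(mnode, "event")))
    warning("SBML events are ignored at load")

  # function definitions (lambda bodies kept as strings)
  fundefs <- list()
  for (fd in sbml_find(mnode, "functionDefinition")) {
    lam <- xml2::xml_find_first(fd, ".//*[local-name()='lambda']")
    kids <- mathml_children(lam)
    bvars <- kids[xml2::xml_name(kids) == "bvar"]
    argn <- vapply(bvars, function(b)
      trimws(xml2::xml_text(xml2::xml_child(b))), "")
    body_node <- kids[[length(kids)]]
    fundefs[[sbml_attr(fd, "id")]] <-
      list(args = argn, body = mathml_to_r(body_node, fundefs))
  }

  comps <- sbml_find(mnode, "compartment")
  compartments <- if (length(comps)) data.frame(
    id = vapply(comps, sbml_attr, "", "id"),
    volume = as.numeric(vapply(comps, sbml_attr, "", "size", "1"))
  ) else data.frame(id = "cell", volume = 1)
  compartments$volume[is.na(compartments$volume)] <- 1
  vol_of <- setNames(compartments$volume, compartments$id)

  spn <- sbml_find(mnode, "species")
  if (length(spn) == 0) stop("SBML format error: model has no species")
  species <- data.frame(
    id = vapply(spn, sbml_attr, "", "id"),
    compartment = vapply(spn, sbml_attr, "", "compartment",
                         compartments$id[1]),
    boundary = vapply(spn, function(s)
      identical(sbml_attr(s, "boundaryCondition", "false"), "true") ||
      identical(sbml_attr(s, "constant", "false"), "true"), TRUE)
  )
  conc <- as.numeric(vapply(spn, sbml_attr, "", "initialConcentration",
                            NA_character_))
  amt <- as.numeric(vapply(spn, sbml_attr, "", "initialAmount",
                           NA_character_))
  init <- ifelse(!is.na(conc), conc,
                 ifelse(!is.na(amt), amt / vol_of[species$compartment], 0))
  species$initial <- unname(init)

  gp <- sbml_find(xml2::xml_find_first(
    mnode, "./*[local-name()='listOfParameters']") , "parameter")
  param_ids <- vapply(gp, sbml_attr, "", "id")
  param_val <- as.numeric(vapply(gp, sbml_attr, "", "value", "NA"))
  parameters <- data.frame(id = param_ids, value = param_val,
                           role = rep("other", length(param_ids)))

  # rules
  assign_rules <- list()
  rate_rules <- list()
  for (rn in sbml_find(mnode, "assignmentRule")) {
    v <- sbml_attr(rn, "variable")
    assign_rules[[v]] <- mathml_to_r(
      xml2::xml_find_first(rn, ".//*[local-name()='math']"), fundefs)
  }
  for (rn in sbml_find(mnode, "rateRule")) {
    v <- sbml_attr(rn, "variable")
    rate_rules[[v]] <- mathml_to_r(
      xml2::xml_find_first(rn, ".//*[local-name()='math']"), fundefs)
  }

  # reactions
  rx <- list()
  for (r in sbml_find(mnode, "reaction")) {
    rid <- sbml_attr(r, "id")
    st <- numeric(0)
    add_side <- function(listname, sign) {
      lst <- xml2::xml_find_first(
        r, paste0("./*[local-name()='", listname, "']"))
      if (inherits(lst, "xml_missing")) return()
      for (sr in xml2::xml_find_all(
        lst, "./*[local-name()='speciesReference']")) {
        if (length(xml2::xml_find_all(
          sr, ".//*[local-name()='stoichiometryMath']")))
          stop("unsupported SBML construct: stoichiometryMath")
        sp_id <- sbml_attr(sr, "species")
        coef <- as.numeric(sbml_attr(sr, "stoichiometry", "1"))
        st[sp_id] <<- (if (sp_id %in% names(st)) st[[sp_id]] else 0) +
          sign * coef
      }
    }
    add_side("listOfReactants", -1)
    add_side("listOfProducts", +1)
    kl <- xml2::xml_find_first(r, "./*[local-name()='kineticLaw']")
    if (inherits(kl, "xml_missing"))
      stop("reaction '", rid, "' has no kinetic law")
    rate <- mathml_to_r(
      xml2::xml_find_first(kl, "./*[local-name()='math']"), fundefs)
    # lift local parameters into the flat list as "<reaction>.<name>"
    locals <- sbml_find(kl, "parameter")
    if (length(locals) == 0) locals <- sbml_find(kl, "localParameter")
    if (length(locals)) {
      lmap <- character(0)
      for (lp in locals) {
        lid <- sbml_attr(lp, "id")
        new_id <- paste0(rid, ".", lid)
        k <- 1
        while (new_id %in% c(parameters$id, species$id, compartments$id)) {
          k <- k + 1
          new_id <- paste0(rid, ".", lid, ".", k)
          warning("local parameter id collision; using '", new_id, "'")
        }
        parameters <- rbind(parameters, data.frame(
          id = new_id, value = as.numeric(sbml_attr(lp, "value", "NA")),
          role = "other"))
        lmap[lid] <- new_id
      }
      rate <- subst_symbols(rate, lmap)
    }
    if (length(st) == 0)
      stop("reaction '", rid, "' has empty stoichiometry")
    rx[[length(rx) + 1]] <- reaction(rid, st, rate)
  }

  # inline assignment rules everywhere (iterate: rules may chain)
  if (length(assign_rules)) {
    for (pass in 1:10) {
      changed <- FALSE
      for (v in names(assign_rules)) {
        for (w in names(assign_rules)) {
          if (v == w) next
          new <- subst_symbols(assign_rules[[w]],
                               setNames(paste0("(", assign_rules[[v]], ")"),
                                        v))
          if (new != assign_rules[[w]]) {
            assign_rules[[w]] <- new
            changed <- TRUE
          }
        }
      }
      if (!changed) break
      if (pass == 10) stop("cyclic assignment rules")
    }
    mapping <- setNames(paste0("(", unlist(assign_rules), ")"),
                        names(assign_rules))
    for (j in seq_along(rx)) rx[[j]]$rate <- str2lang(
      subst_symbols(deparse1(rx[[j]]$rate), mapping))
    for (v in names(rate_rules)) rate_rules[[v]] <-
      subst_symbols(rate_rules[[v]], mapping)
    # assignment-ruled entities are no longer independent parameters/species
    parameters <- parameters[!parameters$id %in% names(assign_rules), ,
                             drop = FALSE]
    species <- species[!species$id %in% names(assign_rules), , drop = FALSE]
  }

  # a rate rule targeting a parameter makes it a dynamic variable
  dyn_par <- intersect(names(rate_rules), parameters$id)
  if (length(dyn_par)) {
    species <- rbind(species, data.frame(
      id = dyn_par, compartment = compartments$id[1], boundary = FALSE,
      initial = parameters$value[match(dyn_par, parameters$id)]))
    parameters <- parameters[!parameters$id %in% dyn_par, , drop = FALSE]
  }

  if (anyNA(parameters$value))
    stop("parameter(s) without a value: ",
         paste(parameters$id[is.na(parameters$value)], collapse = ", "))

  model <- kinetic_model(species = species, reactions = rx,
                         parameters = parameters,
                         compartments = compartments,
                         rate_rules = if (length(rate_rules)) rate_rules
                                      else NULL,
                         id = sbml_attr(mnode, "id", "sbml_model"))
  # tag limiting-rate parameters for MCA
  lr <- limiting_rate_parameters(model)
  model$parameters$role[model$parameters$id %in% stats::na.omit(lr)] <-
    "limiting-rate"
  model
}
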