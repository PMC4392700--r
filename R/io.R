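#' Reading and writing knowledge bases and frame graphs
#'
#' Three on-disk formats are supported. The canonical format is flat JSON,
#' which round-trips the data model exactly and is the reference format for
#' tests. Turtle (a small subset) and N-Triples encode the same content with
#' standard OWL vocabulary: existential restrictions as
#' \code{owl:Restriction}/\code{owl:someValuesFrom} blank nodes,
#' conjunction/disjunction as \code{owl:intersectionOf}/\code{owl:unionOf}
#' lists, the role chain as \code{owl:propertyChainAxiom}. The Turtle writer
#' emits labeled blank nodes and explicit \code{rdf:first}/\code{rdf:rest}
#' triples (no \code{[]}/\code{(...)} sugar) with one triple per line in
#' lexicographic order, so output is bit-stable and the reader stays
#' line-oriented.
#'
#' @name kb_io
NULL

.prefixes <- c(
  rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  owl = "http://www.w3.org/2002/07/owl#",
  fma = "http://purl.org/sig/ont/fma/",
  hco = "http://example.org/hco#",
  data = "http://example.org/data#"
)

.expand_curie <- function(x) {
  ifelse(startsWith(x, "_:"), x, {
    ns <- sub(":.*$", "", x)
    paste0("<", .prefixes[ns], sub("^[^:]+:", "", x), ">")
  })
}

.contract_iri <- function(x, line = NA) {
  if (startsWith(x, "_:")) return(x)
  if (!startsWith(x, "<") || !endsWith(x, ">"))
    stop("parse error", if (!is.na(line)) paste0(" at line ", line),
         ": expected IRI or blank node, got '", x, "'")
  iri <- substr(x, 2, nchar(x) - 1)
  for (ns in names(.prefixes)) {
    base <- .prefixes[[ns]]
    if (startsWith(iri, base))
      return(paste0(ns, ":", substring(iri, nchar(base) + 1)))
  }
  stop("parse error", if (!is.na(line)) paste0(" at line ", line),
       ": IRI outside known namespaces: ", iri)
}

# ---- triple-level encoding of a KB ----

.kb_to_triples <- function(x) {
  stopifnot(inherits(x, "hco_kb"))
  tb <- x$tbox; ab <- x$abox
  out <- list()
  emit <- function(s, p, o) out[[length(out) + 1L]] <<- c(s, p, o)
  counter <- 0L
  bnode <- function() {
    counter <<- counter + 1L
    paste0("_:b", counter)
  }
  list_node <- function(items) {
    head <- "rdf:nil"
    for (it in rev(items)) {
      n <- bnode()
      emit(n, "rdf:first", it)
      emit(n, "rdf:rest", head)
      head <- n
    }
    head
  }
  expr_node <- function(e) {
    if (e$variant == "named") return(e$term)
    n <- bnode()
    switch(e$variant,
      some = {
        emit(n, "rdf:type", "owl:Restriction")
        emit(n, "owl:onProperty", e$property)
        emit(n, "owl:someValuesFrom", expr_node(e$filler))
      },
      and = {
        emit(n, "rdf:type", "owl:Class")
        emit(n, "owl:intersectionOf", list_node(vapply(e$children, expr_node, "")))
      },
      or = {
        emit(n, "rdf:type", "owl:Class")
        emit(n, "owl:unionOf", list_node(vapply(e$children, expr_node, "")))
      })
    n
  }
  for (cl in tb$classes) emit(cl, "rdf:type", "owl:Class")
  for (p in tb$properties) {
    emit(p$name, "rdf:type", "owl:ObjectProperty")
    if (p$transitive) emit(p$name, "rdf:type", "owl:TransitiveProperty")
    if (p$symmetric) emit(p$name, "rdf:type", "owl:SymmetricProperty")
    if (!is.null(p$inverse) && !p$symmetric) emit(p$name, "owl:inverseOf", p$inverse)
    for (sp in p$super_properties) emit(p$name, "rdfs:subPropertyOf", sp)
    if (!is.null(p$domain)) emit(p$name, "rdfs:domain", p$domain)
    if (!is.null(p$range)) emit(p$name, "rdfs:range", p$range)
  }
  for (ax in tb$subclass_axioms)
    emit(ax$lhs, "rdfs:subClassOf", expr_node(ax$rhs))
  for (ax in tb$equivalence_axioms)
    emit(ax$lhs, "owl:equivalentClass", expr_node(ax$rhs))
  for (ch in tb$chain_axioms)
    emit(ch[3], "owl:propertyChainAxiom", list_node(ch[1:2]))
  for (i in ab$individuals) emit(i, "rdf:type", "owl:NamedIndividual")
  for (r in seq_len(nrow(ab$types)))
    emit(ab$types$individual[r], "rdf:type", ab$types$class[r])
  for (r in seq_len(nrow(ab$roles)))
    emit(ab$roles$subject[r], ab$roles$property[r], ab$roles$object[r])
  m <- do.call(rbind, out)
  data.frame(s = m[, 1], p = m[, 2], o = m[, 3], stringsAsFactors = FALSE)
}

.triples_to_kb <- function(tr) {
  is_bnode <- function(x) startsWith(x, "_:")
  pick <- function(s, p) tr$o[tr$s == s & tr$p == p]
  read_list <- function(n) {
    items <- character()
    while (!identical(n, "rdf:nil")) {
      items <- c(items, pick(n, "rdf:first"))
      nxt <- pick(n, "rdf:rest")
      if (length(nxt) != 1) stop("malformed RDF list at ", n)
      n <- nxt
    }
    items
  }
  decode <- function(n) {
    if (!is_bnode(n)) return(ce_named(n))
    op <- pick(n, "owl:onProperty")
    if (length(op) == 1)
      return(ce_some(op, decode(pick(n, "owl:someValuesFrom"))))
    ix <- pick(n, "owl:intersectionOf")
    if (length(ix) == 1)
      return(ce_and(lapply(read_list(ix), decode)))
    ux <- pick(n, "owl:unionOf")
    if (length(ux) == 1)
      return(ce_or(lapply(read_list(ux), decode)))
    stop("undecodable blank node: ", n)
  }
  types_of <- function(s) tr$o[tr$s == s & tr$p == "rdf:type"]
  classes <- sort(unique(tr$s[tr$p == "rdf:type" & tr$o == "owl:Class" &
                                !is_bnode(tr$s)]))
  pnames <- sort(unique(tr$s[tr$p == "rdf:type" & tr$o == "owl:ObjectProperty"]))
  properties <- lapply(pnames, function(p) {
    ty <- types_of(p)
    sym <- "owl:SymmetricProperty" %in% ty
    inv <- pick(p, "owl:inverseOf")
    property_decl(p,
                  inverse = if (sym) p else if (length(inv) == 1) inv,
                  transitive = "owl:TransitiveProperty" %in% ty,
                  symmetric = sym,
                  super_properties = tr$o[tr$s == p & tr$p == "rdfs:subPropertyOf"],
                  domain = {
                    d <- pick(p, "rdfs:domain"); if (length(d) == 1) d
                  },
                  range = {
                    d <- pick(p, "rdfs:range"); if (length(d) == 1) d
                  })
  })
  sub_rows <- which(tr$p == "rdfs:subClassOf" & !is_bnode(tr$s))
  subclass_axioms <- lapply(sub_rows, function(r)
    list(lhs = tr$s[r], rhs = decode(tr$o[r])))
  eq_rows <- which(tr$p == "owl:equivalentClass" & !is_bnode(tr$s))
  equivalence_axioms <- lapply(eq_rows, function(r)
    list(lhs = tr$s[r], rhs = decode(tr$o[r])))
  chain_rows <- which(tr$p == "owl:propertyChainAxiom")
  chain_axioms <- lapply(chain_rows, function(r) {
    items <- read_list(tr$o[r])
    if (length(items) != 2) stop("only length-2 property chains are supported")
    c(items, tr$s[r])
  })
  individuals <- sort(unique(tr$s[tr$p == "rdf:type" &
                                    tr$o == "owl:NamedIndividual"]))
  type_rows <- which(tr$p == "rdf:type" & tr$s %in% individuals &
                       tr$o %in% classes)
  roles_rows <- which(tr$p %in% pnames)
  kb(tbox(classes = classes, properties = properties,
          subclass_axioms = subclass_axioms,
          equivalence_axioms = equivalence_axioms,
          chain_axioms = chain_axioms),
     abox(individuals = individuals,
          types = data.frame(individual = tr$s[type_rows],
                             class = tr$o[type_rows], stringsAsFactors = FALSE),
          roles = data.frame(property = tr$p[roles_rows],
                             subject = tr$s[roles_rows],
                             object = tr$o[roles_rows], stringsAsFactors = FALSE)))
}

# ---- line-level triple serialization ----

.write_triples <- function(tr, path, format) {
  if (format == "ntriples") {
    lines <- paste(.expand_curie(tr$s), .expand_curie(tr$p),
                   .expand_curie(tr$o), ".")
    writeLines(sort(lines), path)
  } else {
    header <- paste0("@prefix ", names(.prefixes), ": <", .prefixes, "> .")
    lines <- paste(tr$s, tr$p, tr$o, ".")
    writeLines(c(header, "", sort(lines)), path)
  }
  invisible(path)
}

.read_triples <- function(path) {
  lines <- readLines(path, warn = FALSE)
  prefixes <- character()
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (startsWith(ln, "@prefix")) {
      m <- regmatches(ln, regexec("^@prefix\\s+([A-Za-z]+):\\s+<([^>]+)>\\s*\\.$", ln))[[1]]
      if (length(m) != 3) stop("parse error at line ", i, ": malformed @prefix")
      prefixes[m[2]] <- m[3]
      next
    }
    if (!grepl("\\.\\s*$", ln))
      stop("parse error at line ", i, ": missing terminating '.'")
    body <- sub("\\s*\\.\\s*$", "", ln)
    toks <- strsplit(body, "\\s+")[[1]]
    if (length(toks) != 3)
      stop("parse error at line ", i, ": expected 3 terms, found ", length(toks))
    term <- function(t) {
      if (startsWith(t, "<")) .contract_iri(t, i)
      else if (startsWith(t, "_:")) t
      else if (grepl("^[A-Za-z]+:[^[:space:]]+$", t)) {
        ns <- sub(":.*$", "", t)
        if (!ns %in% names(.prefixes) && !ns %in% names(prefixes))
          stop("parse error at line ", i, ": unknown prefix '", ns, "'")
        t
      } else stop("parse error at line ", i, ": malformed term '", t, "'")
    }
    rows[[length(rows) + 1L]] <- c(term(toks[1]), term(toks[2]), term(toks[3]))
  }
  m <- do.call(rbind, rows)
  if (is.null(m))
    return(data.frame(s = character(), p = character(), o = character(),
                      stringsAsFactors = FALSE))
  data.frame(s = m[, 1], p = m[, 2], o = m[, 3], stringsAsFactors = FALSE)
}

# ---- JSON encoding ----

.kb_to_list <- function(x) {
  tb <- x$tbox; ab <- x$abox
  list(
    tbox = list(
      classes = tb$classes,
      properties = lapply(tb$properties, function(p) {
        l <- list(name = p$name, transitive = p$transitive,
                  symmetric = p$symmetric,
                  super_properties = as.list(p$super_properties))
        if (!is.null(p$inverse)) l$inverse <- p$inverse
        if (!is.null(p$domain)) l$domain <- p$domain
        if (!is.null(p$range)) l$range <- p$range
        l
      }),
      subclass_axioms = lapply(tb$subclass_axioms, function(ax)
        list(lhs = ax$lhs, rhs = ce_to_list(ax$rhs))),
      equivalence_axioms = lapply(tb$equivalence_axioms, function(ax)
        list(lhs = ax$lhs, rhs = ce_to_list(ax$rhs))),
      chain_axioms = lapply(tb$chain_axioms, as.list)
    ),
    abox = list(
      individuals = ab$individuals,
      type_assertions = unname(lapply(seq_len(nrow(ab$types)), function(r)
        list(ab$types$individual[r], ab$types$class[r]))),
      role_assertions = unname(lapply(seq_len(nrow(ab$roles)), function(r)
        list(ab$roles$property[r], ab$roles$subject[r], ab$roles$object[r])))
    )
  )
}

.kb_from_list <- function(l) {
  tb <- l$tbox
  props <- lapply(unname(tb$properties), function(p)
    property_decl(p$name,
                  inverse = p$inverse,
                  transitive = isTRUE(p$transitive),
                  symmetric = isTRUE(p$symmetric),
                  super_properties = unlist(p$super_properties) %||% character(),
                  domain = p$domain, range = p$range))
  ty <- do.call(rbind, lapply(l$abox$type_assertions, function(a)
    data.frame(individual = a[[1]], class = a[[2]], stringsAsFactors = FALSE)))
  rl <- do.call(rbind, lapply(l$abox$role_assertions, function(a)
    data.frame(property = a[[1]], subject = a[[2]], object = a[[3]],
               stringsAsFactors = FALSE)))
  kb(tbox(classes = unlist(tb$classes) %||% character(),
          properties = props,
          subclass_axioms = lapply(tb$subclass_axioms, function(ax)
            list(lhs = ax$lhs, rhs = ce_from_list(ax$rhs))),
          equivalence_axioms = lapply(tb$equivalence_axioms, function(ax)
            list(lhs = ax$lhs, rhs = ce_from_list(ax$rhs))),
          chain_axioms = lapply(tb$chain_axioms, unlist)),
     abox(individuals = unlist(l$abox$individuals) %||% character(),
          types = ty %||% data.frame(individual = character(), class = character()),
          roles = rl %||% data.frame(property = character(), subject = character(),
                                     object = character())))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.kb_formats <- c("json", "turtle", "ntriples")

.guess_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, .kb_formats))
  switch(tolower(tools::file_ext(path)),
         json = "json", ttl = "turtle", nt = "ntriples",
         stop("cannot guess format from extension of ", path,
              "; pass format explicitly"))
}

#' @rdname kb_io
#' @param x an \code{hco_kb} (or \code{hco_tbox}, wrapped with an empty ABox).
#' @param path file path; extensions \code{.json}, \code{.ttl}, \code{.nt}
#'   imply the format.
#' @param format one of \code{"json"}, \code{"turtle"}, \code{"ntriples"}.
#' @export
write_kb <- function(x, path, format = NULL) {
  if (inherits(x, "hco_tbox")) x <- kb(x)
  stopifnot(inherits(x, "hco_kb"))
  format <- .guess_format(path, format)
  if (format == "json") {
    jsonlite::write_json(.kb_to_list(x), path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  } else {
    .write_triples(.kb_to_triples(x), path, format)
  }
  invisible(path)
}

#' @rdname kb_io
#' @return `read_kb()` returns an \code{hco_kb}; referential-integrity
#'   violations in the file raise an error.
#' @export
read_kb <- function(path, format = NULL) {
  format <- .guess_format(path, format)
  if (format == "json") {
    .kb_from_list(jsonlite::read_json(path))
  } else {
    .triples_to_kb(.read_triples(path))
  }
}

# ---- frame graph IO ----

#' @rdname kb_io
#' @param g an \code{hco_frame_graph}.
#' @export
write_frame_graph <- function(g, path, format = NULL) {
  stopifnot(inherits(g, "hco_frame_graph"))
  format <- .guess_format(path, format)
  if (format == "json") {
    jsonlite::write_json(list(entities = g$entities,
                              triples = g$triples,
                              metaclasses = g$metaclasses),
                         path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    decl <- data.frame(s = g$entities, p = "rdf:type", o = "data:Frame_entity",
                       stringsAsFactors = FALSE)
    meta <- if (length(g$metaclasses) > 0)
      data.frame(s = g$metaclasses, p = "rdf:type", o = "data:Metaclass",
                 stringsAsFactors = FALSE)
    tr <- rbind(decl, meta,
                data.frame(s = g$triples$subject, p = g$triples$predicate,
                           o = g$triples$object, stringsAsFactors = FALSE))
    .write_triples(tr, path, format)
  }
  invisible(path)
}

#' @rdname kb_io
#' @export
read_frame_graph <- function(path, format = NULL) {
  format <- .guess_format(path, format)
  if (format == "json") {
    l <- jsonlite::read_json(path)
    tr <- do.call(rbind, lapply(l$triples, function(t)
      data.frame(subject = t$subject, predicate = t$predicate,
                 object = t$object, stringsAsFactors = FALSE)))
    g <- frame_graph(entities = unlist(l$entities) %||% character(),
                     triples = tr %||% data.frame(subject = character(),
                                                  predicate = character(),
                                                  object = character()),
                     metaclasses = unlist(l$metaclasses) %||% character())
  } else {
    tr <- .read_triples(path)
    is_decl <- tr$p == "rdf:type" & tr$o %in% c("data:Frame_entity", "data:Metaclass")
    entities <- unique(c(tr$s[is_decl], tr$s[!is_decl], tr$o[!is_decl]))
    metaclasses <- tr$s[tr$p == "rdf:type" & tr$o == "data:Metaclass"]
    body <- tr[!is_decl, , drop = FALSE]
    g <- frame_graph(entities = entities,
                     triples = data.frame(subject = body$s, predicate = body$p,
                                          object = body$o,
                                          stringsAsFactors = FALSE),
                     metaclasses = metaclasses)
  }
  # frame sources may assert subsumption as rdf:type to a metaclass; map
  # that pattern onto the distinguished subsumption predicate
  if (length(g$metaclasses) > 0) {
    hit <- g$triples$predicate == "rdf:type" &
      g$triples$object %in% g$metaclasses
    if (any(hit)) {
      g$triples$predicate[hit] <- .subsumption_predicate
      g <- frame_graph(g$entities, g$triples, g$metaclasses)
    }
  }
  g
}
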