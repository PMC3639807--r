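# Turtle and RDF/XML round-trip serialization.
#
# Round-trip contract: parse(serialize(g, f), f) reproduces g's triple set,
# declarations, imports and base IRI for both formats. Declarations and
# imports live in dedicated graph fields; on output they are rendered as
# rdf:type / owl:imports statements, on input those statements are routed
# back into the fields so the triple set itself round-trips exactly.

DECLARATION_CLASSES <- c(
  "concept-class"       = "Class",
  "object-property"     = "ObjectProperty",
  "datatype-property"   = "DatatypeProperty",
  "annotation-property" = "AnnotationProperty",
  "individual"          = "NamedIndividual"
)

declaration_class_iri <- function(kind) owl_iri(DECLARATION_CLASSES[[kind]])

kind_for_declaration_class <- function(class_iri) {
  hit <- names(DECLARATION_CLASSES)[
    paste0(NS_OWL, DECLARATION_CLASSES) == class_iri]
  if (length(hit)) hit else NA_character_
}

xsd_datatype_iri <- function(tag) {
  switch(tag, string = xsd_iri("string"), integer = xsd_iri("integer"),
         stop("unknown literal datatype tag: ", tag, call. = FALSE))
}

datatype_tag_for_iri <- function(dt_iri) {
  if (dt_iri == xsd_iri("integer") || dt_iri == xsd_iri("int")) "integer"
  else "string"
}

# All statements to write: declaration + imports furniture first, then the
# asserted triples.
output_triples <- function(graph) {
  decl <- graph$declarations
  furn <- empty_triples()
  if (length(decl)) {
    furn <- data.frame(
      subject = names(decl), predicate = rdf_iri("type"),
      object = vapply(unname(decl), function(k) declaration_class_iri(k), ""),
      is_literal = FALSE, datatype = NA_character_, stringsAsFactors = FALSE)
  }
  ont <- data.frame(subject = graph$base_iri, predicate = rdf_iri("type"),
                    object = owl_iri("Ontology"), is_literal = FALSE,
                    datatype = NA_character_, stringsAsFactors = FALSE)
  imp <- empty_triples()
  if (length(graph$imports)) {
    imp <- data.frame(subject = graph$base_iri, predicate = owl_iri("imports"),
                      object = graph$imports, is_literal = FALSE,
                      datatype = NA_character_, stringsAsFactors = FALSE)
  }
  rbind(ont, imp, furn, graph$triples)
}

# Route furniture statements parsed from a document back into graph fields.
absorb_parsed_triples <- function(graph, triples) {
  type_p <- rdf_iri("type")
  is_type <- triples$predicate == type_p & !triples$is_literal
  is_ont <- is_type & triples$object == owl_iri("Ontology")
  if (any(is_ont)) graph$base_iri <- triples$subject[which(is_ont)[1L]]

  is_import <- triples$predicate == owl_iri("imports") & !triples$is_literal
  graph$imports <- unique(c(graph$imports, triples$object[is_import]))

  kinds <- rep(NA_character_, nrow(triples))
  kinds[is_type] <- vapply(triples$object[is_type],
                           kind_for_declaration_class, "")
  is_decl <- !is.na(kinds)
  for (i in which(is_decl))
    graph <- declare(graph, triples$subject[i], kinds[i])

  keep <- !(is_ont | is_import | is_decl)
  graph$triples <- empty_triples()
  graph <- add_triples(graph, triples[keep, , drop = FALSE])
  graph
}

# -- Turtle -------------------------------------------------------------------

turtle_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

turtle_unescape <- function(x) {
  x <- gsub("\\t", "\t", x, fixed = TRUE)
  x <- gsub("\\r", "\r", x, fixed = TRUE)
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

pn_local_ok <- function(x) grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", x)

turtle_term <- function(iri_str, prefixes) {
  for (p in names(prefixes)) {
    ns <- prefixes[[p]]
    if (startsWith(iri_str, ns)) {
      loc <- substring(iri_str, nchar(ns) + 1L)
      if (nzchar(loc) && pn_local_ok(loc)) return(paste0(p, ":", loc))
    }
  }
  paste0("<", iri_str, ">")
}

turtle_literal <- function(value, tag) {
  q <- paste0("\"", turtle_escape(value), "\"")
  if (tag == "integer") paste0(q, "^^xsd:integer") else q
}

serialize_turtle <- function(graph) {
  prefixes <- graph$prefixes
  head <- c(
    sprintf("@prefix %s: <%s> .", names(prefixes), unname(prefixes)),
    sprintf("@base <%s> .", graph$base_iri),
    ""
  )
  tr <- output_triples(graph)
  ord <- order(tr$subject, tr$predicate, tr$object)
  tr <- tr[ord, , drop = FALSE]
  lines <- vapply(seq_len(nrow(tr)), function(i) {
    s <- turtle_term(tr$subject[i], prefixes)
    p <- if (tr$predicate[i] == rdf_iri("type")) "a"
         else turtle_term(tr$predicate[i], prefixes)
    o <- if (tr$is_literal[i]) turtle_literal(tr$object[i], tr$datatype[i])
         else turtle_term(tr$object[i], prefixes)
    paste(s, p, o, ".")
  }, "")
  paste0(paste(c(head, lines), collapse = "\n"), "\n")
}

# Tokenize one Turtle statement line into terms, honouring quoted strings.
tokenize_turtle_line <- function(line, lineno) {
  toks <- character(0)
  i <- 1L; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (grepl("^[[:space:]]$", ch)) { i <- i + 1L; next }
    if (ch == "#") break
    if (ch == "<") {
      j <- regexpr(">", substring(line, i))
      if (j < 0) stop("parse error (line ", lineno, "): unterminated IRI",
                      call. = FALSE)
      toks <- c(toks, substr(line, i, i + j - 1L)); i <- i + j
    } else if (ch == "\"") {
      j <- i + 1L
      while (j <= n) {
        cj <- substr(line, j, j)
        if (cj == "\\") { j <- j + 2L; next }
        if (cj == "\"") break
        j <- j + 1L
      }
      if (j > n) stop("parse error (line ", lineno, "): unterminated string",
                      call. = FALSE)
      # attach a ^^datatype suffix if present
      k <- j + 1L
      if (substr(line, k, k + 1L) == "^^") {
        m <- regexpr("^\\^\\^(<[^>]*>|[A-Za-z_][A-Za-z0-9_.-]*:[A-Za-z0-9_.-]+)",
                     substring(line, k))
        if (m < 0) stop("parse error (line ", lineno, "): bad datatype suffix",
                        call. = FALSE)
        k <- k + attr(m, "match.length")
      }
      toks <- c(toks, substr(line, i, k - 1L)); i <- k
    } else if (ch == ".") {
      toks <- c(toks, "."); i <- i + 1L
    } else {
      m <- regexpr("^[^[:space:].]+", substring(line, i))
      # a prefixed local name may contain dots; trailing dot is the terminator
      tok <- regmatches(substring(line, i), m)
      toks <- c(toks, tok); i <- i + attr(m, "match.length")
    }
  }
  toks
}

resolve_turtle_term <- function(tok, prefixes, base, lineno) {
  if (startsWith(tok, "<")) {
    return(list(value = substr(tok, 2L, nchar(tok) - 1L), literal = FALSE))
  }
  if (startsWith(tok, "\"")) {
    m <- regmatches(tok, regexec('^"(.*)"(\\^\\^(.+))?$', tok))[[1]]
    if (!length(m))
      stop("parse error (line ", lineno, "): bad literal token", call. = FALSE)
    value <- turtle_unescape(m[2])
    dt <- "string"
    if (nzchar(m[3])) {
      dt_iri <- resolve_turtle_term(m[4], prefixes, base, lineno)$value
      dt <- datatype_tag_for_iri(dt_iri)
    }
    return(list(value = value, literal = TRUE, datatype = dt))
  }
  if (tok == "a") return(list(value = rdf_iri("type"), literal = FALSE))
  if (grepl("^[0-9]+$", tok))
    return(list(value = tok, literal = TRUE, datatype = "integer"))
  m <- regmatches(tok, regexec("^([A-Za-z_][A-Za-z0-9_.-]*)?:(.*)$", tok))[[1]]
  if (length(m)) {
    if (!m[2] %in% names(prefixes))
      stop("parse error (line ", lineno, "): unknown prefix '", m[2], "'",
           call. = FALSE)
    return(list(value = paste0(prefixes[[m[2]]], m[3]), literal = FALSE))
  }
  stop("parse error (line ", lineno, "): cannot parse term '", tok, "'",
       call. = FALSE)
}

parse_turtle <- function(text, strict = FALSE) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  prefixes <- character(0)
  base <- NULL
  rows <- vector("list", length(lines))
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(trimws(line)) || startsWith(trimws(line), "#")) next
    t <- trimws(line)
    if (startsWith(t, "@prefix")) {
      m <- regmatches(t, regexec("^@prefix[[:space:]]+([A-Za-z_][A-Za-z0-9_.-]*)?:[[:space:]]*<([^>]*)>[[:space:]]*\\.$", t))[[1]]
      if (!length(m)) stop("parse error (line ", ln, "): bad @prefix",
                           call. = FALSE)
      prefixes[m[2]] <- m[3]
      next
    }
    if (startsWith(t, "@base")) {
      m <- regmatches(t, regexec("^@base[[:space:]]*<([^>]*)>[[:space:]]*\\.$", t))[[1]]
      if (!length(m)) stop("parse error (line ", ln, "): bad @base",
                           call. = FALSE)
      base <- m[2]
      next
    }
    toks <- tokenize_turtle_line(line, ln)
    if (!length(toks)) next
    if (length(toks) != 4L || toks[4] != ".")
      stop("parse error (line ", ln,
           "): expected 'subject predicate object .' statement", call. = FALSE)
    s <- resolve_turtle_term(toks[1], prefixes, base, ln)
    p <- resolve_turtle_term(toks[2], prefixes, base, ln)
    o <- resolve_turtle_term(toks[3], prefixes, base, ln)
    if (s$literal || p$literal)
      stop("parse error (line ", ln, "): literal in subject or predicate",
           call. = FALSE)
    rows[[ln]] <- data.frame(
      subject = s$value, predicate = p$value, object = o$value,
      is_literal = isTRUE(o$literal),
      datatype = if (isTRUE(o$literal)) o$datatype else NA_character_,
      stringsAsFactors = FALSE)
  }
  triples <- do.call(rbind, c(list(empty_triples()), rows[!vapply(rows, is.null, TRUE)]))
  g <- ontology_graph(base_iri = if (is.null(base)) "http://purl.example.org/mhbi/schema#" else base,
                      prefixes = if (length(prefixes)) prefixes else default_prefixes(),
                      strict = FALSE)
  g <- absorb_parsed_triples(g, triples)
  g$strict <- strict
  g
}

# -- RDF/XML ------------------------------------------------------------------

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

# Predicate element QName: RDF/XML requires a namespace prefix for property
# elements; unseen namespaces get generated ns1, ns2, ... prefixes.
qname_env <- function(prefixes) {
  env <- new.env(parent = emptyenv())
  env$prefixes <- prefixes
  env$counter <- 0L
  env
}

qname_for <- function(env, iri_str) {
  ns <- iri_namespace(iri_str)
  loc <- iri_local_name(iri_str)
  if (!nzchar(loc) || !pn_local_ok(loc))
    stop("cannot form an XML QName for <", iri_str, ">", call. = FALSE)
  hit <- names(env$prefixes)[env$prefixes == ns]
  if (!length(hit)) {
    env$counter <- env$counter + 1L
    hit <- paste0("ns", env$counter)
    env$prefixes[hit] <- ns
  }
  paste0(hit[1], ":", loc)
}

serialize_rdfxml <- function(graph) {
  env <- qname_env(graph$prefixes)
  tr <- output_triples(graph)
  ord <- order(tr$subject, tr$predicate, tr$object)
  tr <- tr[ord, , drop = FALSE]
  subjects <- unique(tr$subject)
  blocks <- vapply(subjects, function(s) {
    rows <- tr[tr$subject == s, , drop = FALSE]
    props <- vapply(seq_len(nrow(rows)), function(i) {
      q <- qname_for(env, rows$predicate[i])
      if (rows$is_literal[i]) {
        # plain literal for strings (RDF 1.1 equivalent of xsd:string)
        if (rows$datatype[i] == "string") {
          sprintf('    <%s>%s</%s>', q, xml_escape(rows$object[i]), q)
        } else {
          dt <- xsd_datatype_iri(rows$datatype[i])
          sprintf('    <%s rdf:datatype="%s">%s</%s>',
                  q, dt, xml_escape(rows$object[i]), q)
        }
      } else {
        sprintf('    <%s rdf:resource="%s"/>', q, xml_escape(rows$object[i]))
      }
    }, "")
    paste0('  <rdf:Description rdf:about="', xml_escape(s), '">\n',
           paste(props, collapse = "\n"), "\n  </rdf:Description>")
  }, "")
  ns_attrs <- sprintf('    xmlns:%s="%s"', names(env$prefixes),
                      unname(env$prefixes))
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n<rdf:RDF\n',
         paste(ns_attrs, collapse = "\n"), ">\n",
         paste(blocks, collapse = "\n"), "\n</rdf:RDF>\n")
}

parse_rdfxml <- function(text, strict = FALSE) {
  doc <- tryCatch(suppressWarnings(xml2::read_xml(text)),
                  error = function(e) stop("parse error: ", conditionMessage(e),
                                           call. = FALSE))
  prefixes <- unlist(xml2::xml_ns(doc))
  names(prefixes) <- sub("^d1$", "rdf", names(prefixes))
  descriptions <- xml2::xml_find_all(doc, "./*")
  rows <- list()
  for (d in descriptions) {
    s <- xml2::xml_attr(d, "about", ns = character(0))
    if (is.na(s)) s <- xml2::xml_attr(d, "rdf:about")
    ns_map <- xml2::xml_ns(doc)
    for (p in xml2::xml_children(d)) {
      qn <- xml2::xml_name(p, ns = ns_map)
      pred <- paste0(ns_map[[sub(":.*$", "", qn)]], sub("^[^:]*:", "", qn))
      res <- xml2::xml_attr(p, "resource")
      if (!is.na(res)) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, predicate = pred, object = res, is_literal = FALSE,
          datatype = NA_character_, stringsAsFactors = FALSE)
      } else {
        dt_iri <- xml2::xml_attr(p, "datatype")
        dt <- if (is.na(dt_iri)) "string" else datatype_tag_for_iri(dt_iri)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, predicate = pred, object = xml2::xml_text(p),
          is_literal = TRUE, datatype = dt, stringsAsFactors = FALSE)
      }
    }
  }
  triples <- do.call(rbind, c(list(empty_triples()), rows))
  pfx <- prefixes
  g <- ontology_graph(prefixes = pfx, strict = FALSE)
  g <- absorb_parsed_triples(g, triples)
  g$strict <- strict
  g
}

#' Serialize an ontology graph
#'
#' Writes the graph as Turtle or RDF/XML (UTF-8 text). Node-kind
#' declarations are rendered as `rdf:type` statements against the OWL
#' vocabulary and imports as `owl:imports`, so the output is a complete,
#' self-describing OWL document.
#'
#' @param graph An `ontology_graph`.
#' @param format `"turtle"` or `"rdfxml"`.
#' @return A single character string.
#' @seealso [parse_ontology()] for the inverse; the round trip is exact on
#'   the triple set.
#' @export
serialize_ontology <- function(graph, format = c("turtle", "rdfxml")) {
  format <- match.arg(format)
  switch(format, turtle = serialize_turtle(graph),
         rdfxml = serialize_rdfxml(graph))
}

#' Parse an ontology document
#'
#' Reads a Turtle or RDF/XML document produced by [serialize_ontology()] (or
#' a compatible simple document: one statement per line for Turtle,
#' `rdf:Description` blocks for RDF/XML). `rdf:type` statements against the
#' OWL declaration classes are routed into the declarations map and
#' `owl:imports` into the imports list.
#'
#' @param text Document text, or a file path when `file = TRUE`.
#' @param format `"turtle"` or `"rdfxml"`.
#' @param strict Strictness flag of the resulting graph.
#' @param file Treat `text` as a path.
#' @return An `ontology_graph`.
#' @export
parse_ontology <- function(text, format = c("turtle", "rdfxml"),
                           strict = FALSE, file = FALSE) {
  format <- match.arg(format)
  if (file) text <- paste(readLines(text, encoding = "UTF-8", warn = FALSE),
                          collapse = "\n")
  switch(format, turtle = parse_turtle(text, strict),
         rdfxml = parse_rdfxml(text, strict))
}

#' Write an ontology graph to a file
#'
#' Format is inferred from the extension (`.ttl` Turtle, `.owl`/`.rdf`/
#' `.xml` RDF/XML) unless given.
#'
#' @param graph An `ontology_graph`.
#' @param path Output path.
#' @param format Optional explicit format.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(graph, path, format = NULL) {
  if (is.null(format)) format <- format_for_path(path)
  writeLines(serialize_ontology(graph, format), path, useBytes = TRUE)
  invisible(path)
}

#' Read an ontology graph from a file
#' @inheritParams write_ontology
#' @param strict Strictness flag of the resulting graph.
#' @return An `ontology_graph`.
#' @export
read_ontology <- function(path, format = NULL, strict = FALSE) {
  if (is.null(format)) format <- format_for_path(path)
  parse_ontology(path, format, strict = strict, file = TRUE)
}

format_for_path <- function(path) {
  ext <- tolower(sub("^.*\\.", "", path))
  switch(ext, ttl = "turtle", owl = "rdfxml", rdf = "rdfxml", xml = "rdfxml",
         stop("cannot infer RDF format from extension '.", ext,
              "'; pass format=", call. = FALSE))
}
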