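# LIPID MAPS-style shorthand parser: HeadGroup(Sn1/Sn2) or HeadGroup(C:D).

parse_error <- function(name, pos, msg) {
  e <- structure(
    class = c("lipid_parse_error", "error", "condition"),
    list(message = sprintf("cannot parse lipid name '%s' at position %d: %s",
                           name, pos, msg),
         call = NULL, name = name, position = pos)
  )
  stop(e)
}

parse_chain <- function(txt, name, offset) {
  # one acyl/alkyl/sphingoid chain: [O-|P-|d|t]C:D[(dN)]
  m <- regexec("^\\s*(O-|P-|d|t)?([0-9]+):([0-9]+)(?:\\(d([0-9]+)\\))?\\s*$",
               txt)
  g <- regmatches(txt, m)[[1]]
  if (length(g) == 0L) parse_error(name, offset, paste0("bad chain '", txt, "'"))
  list(
    carbons = as.integer(g[3]),
    double_bonds = as.integer(g[4]),
    prefix = g[2],
    deuterium = if (nzchar(g[5])) as.integer(g[5]) else 0L
  )
}

#' Parse lipid shorthand nomenclature
#'
#' Parses names such as `"PC (18:0/18:3)"` (full sn-position form),
#' `"PC(36:3)"` (totals-only shorthand), lyso species (`"LPC (16:0/0:0)"`),
#' ether/plasmanyl (`O-`) and plasmenyl (`P-`) chains, sphingoid-base
#' notation (`"SM(d34:1)"`, `"SM(d18:1/16:0)"`), and deuterium labels
#' (`"PC (15:0/18:1(d7))"`). Whitespace around the headgroup and inside the
#' parentheses is tolerated; an en-dash may stand in for the `/` separator.
#'
#' @param name Lipid name string.
#' @return A list with elements `headgroup`, `chains` (list of
#'   `(carbons, double_bonds)`, or `NULL` in totals-only form),
#'   `total_carbons`, `total_double_bonds`, and logical flags `lyso`, `ether`,
#'   `plasmenyl`, `sphingoid`, `odd_chain`, plus `deuterium` (count of labelled
#'   positions) and `chains_known`.
#' @examples
#' parse_shorthand("PC (18:0/18:3)")
#' parse_shorthand("SM(d34:1)")
#' @export
parse_shorthand <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!nzchar(trimws(name))) parse_error(name, 1L, "empty string")
  # en/em dashes are seen in print as chain separators
  norm <- chartr("–—", "//", name)
  m <- regexec("^\\s*([A-Za-z][A-Za-z0-9-]*?)\\s*\\((.*)\\)\\s*$", norm)
  g <- regmatches(norm, m)[[1]]
  if (length(g) == 0L) {
    parse_error(name, 1L, "expected HeadGroup(...) structure")
  }
  headgroup <- g[2]
  inner <- g[3]
  if (!nzchar(trimws(inner))) {
    parse_error(name, as.integer(regexpr("\\(", norm)) + 1L, "empty chain spec")
  }
  parts <- strsplit(inner, "/", fixed = TRUE)[[1]]
  if (length(parts) > 3L) {
    parse_error(name, 1L, "more than three chains")
  }
  chains <- lapply(parts, parse_chain, name = name,
                   offset = as.integer(regexpr("\\(", norm)) + 1L)

  prefixes <- vapply(chains, `[[`, "", "prefix")
  sphingoid <- any(prefixes %in% c("d", "t"))
  ether <- any(prefixes == "O-")
  plasmenyl <- any(prefixes == "P-")
  carbons <- vapply(chains, `[[`, 0L, "carbons")
  dbs <- vapply(chains, `[[`, 0L, "double_bonds")
  deut <- sum(vapply(chains, `[[`, 0L, "deuterium"))

  totals_only <- length(chains) == 1L
  lyso <- !totals_only && any(carbons == 0L & dbs == 0L)
  chain_list <- if (totals_only) NULL else
    lapply(chains, function(ch) c(carbons = ch$carbons,
                                  double_bonds = ch$double_bonds))

  list(
    headgroup = headgroup,
    chains = chain_list,
    total_carbons = sum(carbons),
    total_double_bonds = sum(dbs),
    lyso = lyso,
    ether = ether,
    plasmenyl = plasmenyl,
    sphingoid = sphingoid,
    deuterium = deut,
    odd_chain = sum(carbons) %% 2L == 1L,
    chains_known = !totals_only
  )
}
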