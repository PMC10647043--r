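#' Transformation rule set for azologization and azoextension
#'
#' Builds the named rule list driving the photoswitch enumeration. Five
#' categories are supported:
#' \describe{
#'   \item{typical_azologization}{two (hetero)aromatic rings joined by a
#'     two-atom unbranched acyclic linker (any linker element among
#'     \code{linker_elements}, any bond order); the linker becomes N=N.}
#'   \item{atypical_azologization}{ring-ring single bond (0-atom linker),
#'     one-atom linker with at most a one-atom branch, and three-atom linker
#'     where each linker atom may bear one extra terminal atom; the linker
#'     (with branches) becomes N=N.}
#'   \item{naphthalene_azologization}{a mono- or disubstituted fused 6-6
#'     fully aromatic bicycle is replaced by azobenzene, with the
#'     substituent(s) placed exhaustively over the azobenzene ring positions
#'     (rule names encode parent and product positions).}
#'   \item{typical_azoextension}{a phenyldiazene (-N=N-C6H5) is appended at
#'     every free aromatic C-H position.}
#'   \item{atypical_azoextension}{a substituent of at most
#'     \code{max_replaced_substituent} heavy atoms on an aromatic carbon is
#'     replaced by phenyldiazene.}
#' }
#'
#' Each rule carries a SMARTS reaction string describing the transformation;
#' matching and graph editing are performed by the package's graph engine,
#' with the SMARTS retained for export and validation.
#'
#' @param categories character vector of category names (see above).
#' @param naphthalene_mode one of "mono", "di", "both": which substitution
#'   counts of the bicycle are transformed.
#' @param max_replaced_substituent 1, 2 or 3: maximum heavy-atom size of a
#'   substituent displaced by atypical azoextension.
#' @param linker_elements elements allowed as azologization linker atoms.
#' @return a data.frame of class \code{psw_rule_set} with columns
#'   \code{name}, \code{category}, \code{reaction}, \code{linker_length},
#'   \code{param}.
#' @export
build_rule_set <- function(categories = c("typical_azologization",
                                          "atypical_azologization",
                                          "naphthalene_azologization",
                                          "typical_azoextension",
                                          "atypical_azoextension"),
                           naphthalene_mode = c("both", "mono", "di"),
                           max_replaced_substituent = 1,
                           linker_elements = c("C", "N", "O", "S")) {
  valid <- c("typical_azologization", "atypical_azologization",
             "naphthalene_azologization", "typical_azoextension",
             "atypical_azoextension")
  bad <- setdiff(categories, valid)
  if (length(categories) == 0 || length(bad) > 0)
    stop("invalid rule category: ", paste(bad, collapse = ", "))
  naphthalene_mode <- match.arg(naphthalene_mode)
  if (!max_replaced_substituent %in% 1:3)
    stop("max_replaced_substituent must be 1, 2 or 3")

  lk <- paste0("[", paste(linker_elements, collapse = ","), ";A;!R]")
  rows <- list()
  add <- function(name, category, reaction, linker_length = NA, param = NA_character_) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, category = category, reaction = reaction,
      linker_length = linker_length, param = param, stringsAsFactors = FALSE)
  }
  if ("typical_azologization" %in% categories)
    add("Azolog_2atom", "typical_azologization",
        paste0("[a:1]!@", lk, "!@", lk, "!@[a:2]>>[a:1]/N=N/[a:2]"), 2)
  if ("atypical_azologization" %in% categories) {
    add("Azolog_0atom", "atypical_azologization",
        "[a:1]!@[a:2]>>[a:1]/N=N/[a:2]", 0)
    add("Azolog_1atom", "atypical_azologization",
        paste0("[a:1]!@", lk, "!@[a:2]>>[a:1]/N=N/[a:2]"), 1,
        param = "branch<=1")
    add("Azolog_3atom", "atypical_azologization",
        paste0("[a:1]!@", lk, "!@", lk, "!@", lk, "!@[a:2]>>[a:1]/N=N/[a:2]"), 3,
        param = "branch<=1 per linker atom")
  }
  if ("naphthalene_azologization" %in% categories) {
    if (naphthalene_mode %in% c("mono", "both"))
      add("Naphtho_mono_ABz", "naphthalene_azologization",
          "[*:3]-c(:a)1aaac2aaaac12>>[*:3]-c1ccc(cc1)/N=N/c1ccccc1",
          param = "mono; exhaustive placement")
    if (naphthalene_mode %in% c("di", "both"))
      add("Naphtho_di_ABz", "naphthalene_azologization",
          "[*:3]-c1aac2aac([*:4])aac2a1>>[*:3]-c1ccc(cc1)/N=N/c1ccc([*:4])cc1",
          param = "di; exhaustive placement")
  }
  if ("typical_azoextension" %in% categories)
    add("Azoext_typical", "typical_azoextension",
        "[cH:1]>>[c:1]/N=N/c1ccccc1")
  if ("atypical_azoextension" %in% categories)
    add(paste0("Azoext_atypical_", max_replaced_substituent),
        "atypical_azoextension",
        "[c:1]-[!#1]>>[c:1]/N=N/c1ccccc1",
        param = paste0("replaced<=", max_replaced_substituent))

  out <- do.call(rbind, rows)
  attr(out, "naphthalene_mode") <- naphthalene_mode
  attr(out, "max_replaced_substituent") <- max_replaced_substituent
  attr(out, "linker_elements") <- linker_elements
  class(out) <- c("psw_rule_set", "data.frame")
  out
}

#' Validate the SMARTS of a rule set
#'
#' Splits each reaction on \code{>>} and checks that OpenBabel accepts both
#' sides as SMARTS patterns, and that the product pattern places an azo bond
#' between two aromatic atoms.
#'
#' @param rules a \code{psw_rule_set}.
#' @return invisibly TRUE; stops on an invalid SMARTS.
#' @export
validate_rule_set <- function(rules) {
  probe <- ChemmineOB::forEachMol("SMILES", "c1ccc(cc1)/N=N/c1ccccc1\tazb", identity)
  for (i in seq_len(nrow(rules))) {
    sides <- strsplit(rules$reaction[i], ">>", fixed = TRUE)[[1]]
    if (length(sides) != 2) stop("rule ", rules$name[i], ": not a reaction SMARTS")
    for (s in sides) {
      pat <- gsub(":[0-9]+", "", s)
      n <- tryCatch(ChemmineOB::smartsSearch_OB(probe, pat, uniqueMatches = TRUE),
                    error = function(e) stop("rule ", rules$name[i],
                                             ": SMARTS does not parse: ", s))
    }
    if (!grepl("N=N", sides[2], fixed = TRUE))
      stop("rule ", rules$name[i], ": product pattern lacks an azo bond")
  }
  invisible(TRUE)
}

#' Export a rule set as a text file of named SMARTS reactions
#' @param rules a \code{psw_rule_set}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_rule_set <- function(rules, path) {
  writeLines(sprintf("%s\t%s\t%s", rules$name, rules$category, rules$reaction), path)
  invisible(path)
}

#' @export
print.psw_rule_set <- function(x, ...) {
  cat("<psw_rule_set>", nrow(x), "rules:\n")
  for (i in seq_len(nrow(x))) cat("  ", x$name[i], " [", x$category[i], "]\n", sep = "")
  invisible(x)
}
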