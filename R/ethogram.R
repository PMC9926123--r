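#' Ethogram of scored home-cage behaviors
#'
#' The catalogue of behaviors scored in the visible burrow system (VBS) by
#' scan sampling, with their category (affiliative, aggressive, sexual,
#' defensive, maintenance) and the grouped label used for counting and
#' network construction. All aggressive behaviors except struggling at the
#' feeder are grouped under `general_aggression`; mounting and embracing
#' under `sexual`; the three sniffing variants under `sniffing`.
#'
#' @return A data.frame with columns `behavior`, `category`, `grouped` and
#'   `dyadic` (logical: whether a receiver is required).
#' @export
#' @examples
#' e <- vbs_ethogram()
#' table(e$category)
vbs_ethogram <- function() {
  e <- rbind(
    data.frame(behavior = "allogrooming",         category = "affiliative", grouped = "allogrooming"),
    data.frame(behavior = "attending",            category = "affiliative", grouped = "attending"),
    data.frame(behavior = "huddle",               category = "affiliative", grouped = "huddling"),
    data.frame(behavior = "sniffing_anogenital",  category = "affiliative", grouped = "sniffing"),
    data.frame(behavior = "sniffing_nose",        category = "affiliative", grouped = "sniffing"),
    data.frame(behavior = "sniffing_body",        category = "affiliative", grouped = "sniffing"),
    data.frame(behavior = "struggling_at_feeder", category = "aggressive",  grouped = "struggling_at_feeder"),
    data.frame(behavior = "aggressive_grooming",  category = "aggressive",  grouped = "general_aggression"),
    data.frame(behavior = "attack",               category = "aggressive",  grouped = "general_aggression"),
    data.frame(behavior = "following",            category = "aggressive",  grouped = "general_aggression"),
    data.frame(behavior = "fight",                category = "aggressive",  grouped = "general_aggression"),
    data.frame(behavior = "mutual_upright",       category = "aggressive",  grouped = "general_aggression"),
    data.frame(behavior = "pinning",              category = "aggressive",  grouped = "general_aggression"),
    data.frame(behavior = "struggle_in_tunnels",  category = "aggressive",  grouped = "general_aggression"),
    data.frame(behavior = "mounting",             category = "sexual",      grouped = "sexual"),
    data.frame(behavior = "embracing",            category = "sexual",      grouped = "sexual"),
    data.frame(behavior = "flight",               category = "defensive",   grouped = "defensive"),
    data.frame(behavior = "freezing",             category = "defensive",   grouped = "defensive"),
    data.frame(behavior = "lateral_defense",      category = "defensive",   grouped = "defensive"),
    data.frame(behavior = "supine_posture",       category = "defensive",   grouped = "defensive"),
    data.frame(behavior = "upright_defense",      category = "defensive",   grouped = "defensive"),
    data.frame(behavior = "drinking",             category = "maintenance", grouped = "drinking"),
    data.frame(behavior = "eating",               category = "maintenance", grouped = "eating"),
    data.frame(behavior = "grooming",             category = "maintenance", grouped = "grooming")
  )
  # receiver required for dyadic categories: affiliative, aggressive, sexual.
  # maintenance is solitary; defensive may or may not have an identified
  # opponent (freezing has none, flight usually does), so it is optional.
  e$dyadic <- e$category %in% c("affiliative", "aggressive", "sexual")
  e
}

#' Map behavior labels to grouped category or top-level category
#'
#' @param behavior character vector of ethogram behavior labels.
#' @param to `"grouped"` or `"category"`.
#' @return character vector of the same length.
#' @export
behavior_group <- function(behavior, to = c("grouped", "category")) {
  to <- match.arg(to)
  e <- vbs_ethogram()
  idx <- match(behavior, e$behavior)
  if (anyNA(idx)) {
    bad <- unique(behavior[is.na(idx)])
    stop("unknown behavior label(s): ", paste(bad, collapse = ", "))
  }
  e[[if (to == "grouped") "grouped" else "category"]][idx]
}
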