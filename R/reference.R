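# Published confusion counts of the Dutch TT1 screening programme.

#' Published confusion counts per screening protocol and period
#'
#' The confirmed outcome counts reported for the Dutch programme: one row
#' per era of the national protocol history (2007 tyrosine screening, the
#' two NeoBase-era SA cut-offs, the pooled NeoBase era, the current
#' NeoBase 2 period) and one row per protocol evaluated on the enriched
#' dataset (current rule and alternatives L, N, O). These counts are the
#' published inputs from which all performance indicators derive; passing a
#' row through [confusion_counts()] and [screen_metrics()] reproduces the
#' printed indicator cells.
#'
#' @return data frame with columns `id`, `period`, `protocol`, `tn`, `fn`,
#'   `tp`, `fp`.
#' @examples
#' rc <- reference_counts()
#' with(rc[rc$id == "nb2_2018_2021", ],
#'      print(screen_metrics(confusion_counts(tp, fp, tn, fn))))
#' @export
reference_counts <- function() {
  data.frame(
    id = c("tyr500_2007", "sa15_2008_2009", "sa12_2009_2017",
           "neobase_era_total", "nb2_2018_2021",
           "enriched_current", "enriched_alt_L", "enriched_alt_N",
           "enriched_alt_O"),
    period = c("2007-01/2007-02", "2008-10/2009-06", "2009-07/2017-12",
               "2008-10/2017-12", "2018-01/2021-12",
               rep("enriched 2008-2024", 4)),
    protocol = c("tyr500_2007", "sa15_2008", "sa12_2009",
                 "NeoBase era pooled", "sa060_current",
                 "sa060_current", "alt_L", "alt_N", "alt_O"),
    tn = c(34099, 136641, 1506912, 1643553, 693798,
           653396, 653515, 653516, 653518),
    fn = c(0, 0, 1, 1, 0, 0, 0, 0, 0),
    tp = c(0, 1, 8, 9, 2, 13, 13, 13, 13),
    fp = c(12, 2, 14, 16, 21, 127, 8, 7, 5),
    stringsAsFactors = FALSE
  )
}
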