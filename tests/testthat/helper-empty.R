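empty_courses_fixture <- function() {
  courses_from_counts(tibble::tibble(index_drug = character(),
                                     pattern = character(), n = integer()))
}
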