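# Drug-name normalization rules for the eleven mu-opioid receptor agonists
# approved in Japan. A verbatim drug-name string receives a label when some
# include pattern is a case-insensitive substring of it and no exclude pattern
# is. Salt/hydrate suffixes (SULFATE, HYDROCHLORIDE, HYDRATE, ...) therefore
# match automatically by substring containment.
#
# Exclusions resolve name collisions:
#   - APOMORPHINE contains MORPHINE but is a dopamine agonist, not an opioid.
#   - DIHYDROCODEINE contains CODEINE and must not count as codeine.
#   - The fentanyl rule excludes remifentanil spellings; canonical
#     "REMIFENTANIL" does not contain "FENTANYL", but the misspelling
#     "REMIFENTANYL" occurs in verbatim strings and would otherwise match.
# HYDROMORPHONE does not collide with MORPHINE ("MORPHONE" != "MORPHINE");
# ALFENTANIL/SUFENTANIL/CARFENTANIL contain "FENTANIL", not "FENTANYL".
# Pethidine is listed as MEPERIDINE in US reports; both spellings map to it.
- label: morphine
  include: [MORPHINE]
  exclude: [APOMORPHINE]
- label: fentanyl
  include: [FENTANYL]
  exclude: [REMIFENTANYL, REMIFENTANIL]
- label: oxycodone
  include: [OXYCODONE]
  exclude: []
- label: codeine
  include: [CODEINE]
  exclude: [DIHYDROCODEINE]
- label: dihydrocodeine
  include: [DIHYDROCODEINE]
  exclude: []
- label: hydromorphone
  include: [HYDROMORPHONE]
  exclude: []
- label: methadone
  include: [METHADONE]
  exclude: []
- label: tapentadol
  include: [TAPENTADOL]
  exclude: []
- label: pethidine
  include: [PETHIDINE, MEPERIDINE]
  exclude: []
- label: loperamide
  include: [LOPERAMIDE]
  exclude: []
- label: remifentanil
  include: [REMIFENTANIL]
  exclude: []
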