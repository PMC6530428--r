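{
  "context_id": "economics",
  "event_a_label": "attends economics course",
  "event_b_label": "career-oriented",
  "cells": [0.2, 0.05, 0.3, 0.45],
  "population_n": 1000,
  "note": "synthetic reconstruction from the published cell values 20%, 5%, 45% and counts 300/200 of N=1,000; the fourth cell follows by normalization"
}
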