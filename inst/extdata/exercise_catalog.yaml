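# Default exercise catalog: 35 computerized cognitive training exercises and
# the baseline assessment battery, mapped onto seven cognitive domains.
# Each exercise is classified by the single predominant domain it loads on.
#
# Note on counts: the delivery platform's accompanying prose describes "34
# stand-alone exercises", but the published domain/exercise table enumerates
# 35 exercise names. This file ships the full enumeration (35) because the
# table is the only complete listing available; whether one entry was merged
# or dropped in production is unknown.
#
# The baseline battery comprises eight test scores; the two Visual Memory
# instruments (Cogstate One Card Learning and Cambridge Brain Sciences Paired
# Associates) are treated as a single composite assessment at intake so that
# each domain contributes one number to the cognitive profile.
exercises:
  - {id: memory_interrupted, name: "Memory interrupted", domain: VerbalMemory}
  - {id: memo_pair, name: "Memo pair", domain: VerbalMemory}
  - {id: verbal_learning, name: "Verbal learning", domain: VerbalMemory}
  - {id: eagle_eye, name: "Eagle eye", domain: VisualAttention}
  - {id: clockwise, name: "Clockwise", domain: VisualAttention}
  - {id: memobox, name: "Memobox", domain: VisualAttention}
  - {id: quick_count, name: "Quick count", domain: VisualAttention}
  - {id: quick_switch, name: "Quick switch", domain: VisualAttention}
  - {id: path_finder, name: "Path finder", domain: VisualMemory}
  - {id: path_finder_reverse, name: "Path finder reverse", domain: VisualMemory}
  - {id: restorer, name: "Restorer", domain: VisualMemory}
  - {id: focus_master, name: "Focus master", domain: VisualMemory}
  - {id: polaroid_picture, name: "Polaroid picture", domain: VisualMemory}
  - {id: symbolism, name: "Symbolism", domain: VisualMemory}
  - {id: turnabout, name: "Turnabout", domain: VisualMemory}
  - {id: reflector, name: "Reflector", domain: VisualMemory}
  - {id: word_craft, name: "Word craft", domain: VerbalExecutive}
  - {id: scrambled_words, name: "Scrambled words", domain: VerbalExecutive}
  - {id: domino_word, name: "Domino word", domain: VerbalExecutive}
  - {id: password, name: "Password", domain: VerbalExecutive}
  - {id: plastic_puzzle, name: "Plastic puzzle", domain: VisualExecutive}
  - {id: solitaria, name: "Solitaria", domain: VisualExecutive}
  - {id: escalator, name: "Escalator", domain: VisualExecutive}
  - {id: color_craze, name: "Color craze", domain: VisualExecutive}
  - {id: rotator, name: "Rotator", domain: VisualExecutive}
  - {id: form_fusion, name: "Form fusion", domain: VisualExecutive}
  - {id: missing_link, name: "Missing link", domain: VisualExecutive}
  - {id: parita_speed, name: "Parita speed", domain: WorkingMemory}
  - {id: form_fever, name: "Form fever", domain: WorkingMemory}
  - {id: mixed_memories, name: "Mixed memories", domain: WorkingMemory}
  - {id: split_second, name: "Split second", domain: ProcessingSpeed}
  - {id: flash_glance, name: "Flash glance", domain: ProcessingSpeed}
  - {id: form_fever_speed, name: "Form fever speed", domain: ProcessingSpeed}
  - {id: turning_tables, name: "Turning tables", domain: ProcessingSpeed}
  - {id: alphabet_soup, name: "Alphabet soup", domain: ProcessingSpeed}
assessments:
  - {id: logos_verbal_memory, domain: VerbalMemory,
     source_name: "LOGOS (automated verbal memory test)"}
  - {id: cogstate_identification, domain: VisualAttention,
     source_name: "Cogstate - Identification"}
  - {id: visual_memory_composite, domain: VisualMemory,
     source_name: "Cogstate - One card learning + Cambridge Brain Sciences - Paired associates (composite)"}
  - {id: cbs_grammatical_reasoning, domain: VerbalExecutive,
     source_name: "Cambridge Brain Sciences - Grammatical reasoning"}
  - {id: cbs_spatial_search, domain: VisualExecutive,
     source_name: "Cambridge Brain Sciences - Spatial search"}
  - {id: cogstate_one_back, domain: WorkingMemory,
     source_name: "Cogstate - One-back test"}
  - {id: cogstate_detection, domain: ProcessingSpeed,
     source_name: "Cogstate - Detection"}
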