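# Default evolutionary-origin categories for plastid-protein tree sorting.
# The alveolate category requires a non-dinoflagellate alveolate (ciliate)
# witness so that pure dinoflagellate clades remain plastid-early.
- name: plastid-late
  member_group: haptophytes
- name: plastid-early
  member_group: dinoflagellates
- name: alveolate
  member_group: alveolates
  required_witness_group: ciliates
- name: green-LGT
  member_group: green
- name: brown-LGT
  member_group: ochrophytes
- name: prokaryote-LGT
  member_group: prokaryotes
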