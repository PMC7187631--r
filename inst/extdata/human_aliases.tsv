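# Optional human-related aliases (off by default): words that usually imply
# human subjects but are not species names in the strict sense. Enable with
# compile_default_lexicon(include_human_aliases = TRUE).
Human	patient
Human	patients
Human	man
Human	men
Human	woman
Human	women
Human	male
Human	males
Human	female
Human	females
Human	humankind
Human	humanity
Human	humane
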