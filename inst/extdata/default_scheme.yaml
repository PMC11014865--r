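# Default taxon scheme: fucoxanthin-dinoflagellate plastid proteome sorting.
# Leaves follow the "<dataset>_<serial>" convention (arbitrary suffixes
# tolerated); rules are regenerated from dataset ids.
seed_lineage: Kareniaceae
seed_lineage_neutral: true
groups:
  alveolates: ~
  dinoflagellates: alveolates
  ciliates: alveolates
  Kareniaceae: dinoflagellates
  fucoxanthin: Kareniaceae
  Karenia: fucoxanthin
  Karlodinium: fucoxanthin
  Takayama: fucoxanthin
  haptophytes: ~
  Chrysochromulinaceae: haptophytes
  Isochrysidales: haptophytes
  Prymnesiales: haptophytes
  Phaeocystales: haptophytes
  Coccolithales: haptophytes
  Pavlovales: haptophytes
  green: ~
  ochrophytes: ~
  prokaryotes: ~
  eubacteria: prokaryotes
  archaea: prokaryotes
  metazoa: ~
datasets:
  Karenia_mikimotoi: [Karenia]
  Karenia_brevis: [Karenia]
  Karenia_papilionacea: [Karenia]
  Karlodinium_micrum: [Karlodinium]
  Karlodinium_armiger: [Karlodinium]
  Takayama_helix: [Takayama]
  Symbiodinium_microadriaticum: [dinoflagellates]
  Heterocapsa_triquetra: [dinoflagellates]
  Amphidinium_carterae: [dinoflagellates]
  Tetrahymena_thermophila: [ciliates]
  Paramecium_tetraurelia: [ciliates]
  Emiliania_huxleyi: [Isochrysidales]
  Gephyrocapsa_oceanica: [Isochrysidales]
  Chrysochromulina_tobinii: [Chrysochromulinaceae]
  Chrysochromulina_parva: [Chrysochromulinaceae]
  Prymnesium_parvum: [Prymnesiales]
  Haptolina_brevifila: [Prymnesiales]
  Phaeocystis_antarctica: [Phaeocystales]
  Phaeocystis_globosa: [Phaeocystales]
  Coccolithus_pelagicus: [Coccolithales]
  Calcidiscus_leptoporus: [Coccolithales]
  Pavlova_lutheri: [Pavlovales]
  Exanthemachrysis_gayraliae: [Pavlovales]
  Chlamydomonas_reinhardtii: [green]
  Arabidopsis_thaliana: [green]
  Bigelowiella_natans: [green]
  Phaeodactylum_tricornutum: [ochrophytes]
  Ectocarpus_siliculosus: [ochrophytes]
  Nannochloropsis_gaditana: [ochrophytes]
  Escherichia_coli: [eubacteria]
  Synechocystis_sp: [eubacteria]
  Sulfolobus_solfataricus: [archaea]
  Homo_sapiens: [metazoa]
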