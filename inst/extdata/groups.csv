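group,member
archaboilinae,Archaboilus shurabicus
archaboilinae,Archaboilus martynovi
archaboilinae,Archaboilus musicus
archaboilinae,Archaboilus polyneurus
archaboilinae,Archaboilus ornatus sp. n.
archaboilinae,Tasgorosailus orlovskajae
archaboilinae,Pararchaboilus cretaceus
archaboilinae,Vitimoilus captiosus
archaboilinae,Vitimoilus ovatus
archaboilinae,Vitmoilus gigantus sp. n.
vitimoilus,Vitimoilus captiosus
vitimoilus,Vitimoilus ovatus
vitimoilus,Vitmoilus gigantus sp. n.
archaboilus_core,Archaboilus shurabicus
archaboilus_core,Archaboilus martynovi
archaboilus_core,Archaboilus musicus
archaboilus_core,Archaboilus ornatus sp. n.
cyrtophyllitinae_sensu_lato,Archaboilus shurabicus
cyrtophyllitinae_sensu_lato,Archaboilus martynovi
cyrtophyllitinae_sensu_lato,Archaboilus musicus
cyrtophyllitinae_sensu_lato,Archaboilus polyneurus
cyrtophyllitinae_sensu_lato,Archaboilus ornatus sp. n.
cyrtophyllitinae_sensu_lato,Tasgorosailus orlovskajae
cyrtophyllitinae_sensu_lato,Pararchaboilus cretaceus
cyrtophyllitinae_sensu_lato,Cyrtophyllites rogeri
cyrtophyllitinae_sensu_lato,Vitimoilus captiosus
cyrtophyllitinae_sensu_lato,Vitimoilus ovatus
cyrtophyllitinae_sensu_lato,Vitmoilus gigantus sp. n.
rogeri_caii,Cyrtophyllites rogeri
rogeri_caii,Liassophyllum caii
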