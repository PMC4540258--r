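group,taxon,deposit,n
otter_tail,otter,tail,46
otter_footpad,otter,footpad,19
crayfish,crayfish,none,14
frog,frog,none,12
mollusc,mollusc,none,37
fish_clup,fish,none,6
fish_cypr,fish,none,15
fish_perc,fish,none,43
fish_silur,fish,none,26
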