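drug_name,factor
levodopa,1.0
levodopa_cr,0.75
levodopa_entacapone,1.33
pramipexole,100
pramipexole_er,100
ropinirole,20
ropinirole_xl,20
rotigotine,30
apomorphine,10
rasagiline,100
selegiline,10
safinamide,1.0
amantadine,1.0
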