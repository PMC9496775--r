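# Domain expansion list: frequent but uninformative tokens in Italian
# pandemic-narrative text. Mirrors the practice of massively expanding the
# library stopword lists before topic modeling.
cosa
cose
fatto
fatti
giorno
giorni
settimana
settimane
mese
mesi
anno
anni
volta
volte
modo
parte
momento
momenti
vita
casa
persona
persone
essere
stare
fare
dire
detto
andare
andato
venire
venuto
vedere
visto
sentire
sentito
pensare
pensato
sapere
potere
dovere
volere
grazie
ecco
cioe
ovvero
circa
verso
senza
dentro
fuori
sopra
sotto
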