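# Base Italian function-word stopword list (Snowball-style).
# One token per line; '#' starts a comment.
a
ad
al
allo
ai
agli
all
agl
alla
alle
con
col
coi
da
dal
dallo
dai
dagli
dall
dagl
dalla
dalle
di
del
dello
dei
degli
dell
degl
della
delle
in
nel
nello
nei
negli
nell
negl
nella
nelle
su
sul
sullo
sui
sugli
sull
sugl
sulla
sulle
per
tra
fra
contro
io
tu
lui
lei
noi
voi
loro
mio
mia
miei
mie
tuo
tua
tuoi
tue
suo
sua
suoi
sue
nostro
nostra
nostri
nostre
vostro
vostra
vostri
vostre
mi
ti
ci
vi
lo
la
li
le
gli
ne
il
un
uno
una
ma
ed
se
perche
anche
come
dov
dove
che
chi
cui
non
piu
quale
quanto
quanti
quanta
quante
quello
quelli
quella
quelle
questo
questi
questa
queste
si
tutto
tutti
e
sono
sei
siamo
siete
sia
siate
siano
saro
sarai
sara
saremo
sarete
saranno
sarei
saresti
sarebbe
saremmo
sareste
sarebbero
ero
eri
era
eravamo
eravate
erano
fui
fosti
fu
fummo
foste
furono
fossi
fosse
fossimo
fossero
essendo
stato
stata
stati
state
ho
hai
ha
abbiamo
avete
hanno
abbia
abbiate
abbiano
avro
avrai
avra
avremo
avrete
avranno
avrei
avresti
avrebbe
avremmo
avreste
avrebbero
avevo
avevi
aveva
avevamo
avevate
avevano
ebbi
avesti
ebbe
avemmo
aveste
ebbero
avessi
avesse
avessimo
avessero
avendo
avuto
avuta
avuti
avute
faccio
fai
facciamo
fanno
faccia
facciate
facciano
faro
farai
fara
faremo
farete
faranno
fare
fatto
sto
stai
sta
stiamo
stanno
stare
o
od
al
quindi
allora
pero
dopo
prima
ancora
gia
mai
sempre
poi
qui
qua
li
ora
oggi
ieri
molto
poco
tanto
troppo
solo
cosi
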