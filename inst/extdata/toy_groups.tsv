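category	group
i	pronouns
we	pronouns
you	pronouns
shehe	pronouns
they	pronouns
posemo	emotion
negemo	emotion
anx	emotion
anger	emotion
sad	emotion
assent	attitude
negate	attitude
compare	attitude
certain	attitude
tentat	attitude
differ	attitude
interrog	attitude
cogproc	cognition
insight	cognition
cause	cognition
discrep	cognition
percept	perception
see	perception
feel	perception
hear	perception
bio	biology
body	biology
health	biology
ingest	biology
sleep	biology
social	social
family	social
friend	social
female	social
male	social
drives	drives
affiliation	drives
achieve	drives
power	drives
reward	drives
risk	drives
work	drives
money	drives
relig	drives
death	drives
relativ	relativity
motion	relativity
space	relativity
time	relativity
focuspast	relativity
focuspresent	relativity
focusfuture	relativity
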